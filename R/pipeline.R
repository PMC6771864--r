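# End-to-end orchestration: build the harmonized weight tables (QC ->
# match -> p-select -> clump -> APOE-region exclusion), assemble the score
# set, run every contrast's model battery and the pathway batteries, and
# write the on-disk dataset / report bundle.

#' Subset a dosage_matrix by sample indices or variant ids
#'
#' @param dm a `dosage_matrix`.
#' @param rows integer/logical sample indices (NULL = all).
#' @param snp_ids variant ids to keep (NULL = all).
#' @export
subset_dosages <- function(dm, rows = NULL, snp_ids = NULL) {
  stopifnot(inherits(dm, "dosage_matrix"))
  if (!is.null(rows)) {
    dm$dosages <- dm$dosages[rows, , drop = FALSE]
    dm$samples <- dm$samples[rows, , drop = FALSE]
  }
  if (!is.null(snp_ids)) {
    keep <- dm$variants$id %in% snp_ids
    dm$dosages <- dm$dosages[, keep, drop = FALSE]
    dm$variants <- dm$variants[keep, , drop = FALSE]
  }
  dm
}

#' Build the harmonized, selected, clumped weight tables
#'
#' Fixed pipeline order: variant QC in the target sample -> allele
#' harmonization against the discovery summary statistics -> p-value
#' selection (`p <= p_max`) -> greedy LD clumping (r2, window) -> APOE
#' region exclusion. Returns every intermediate table plus stage-wise
#' variant counts.
#'
#' @param dosages target `dosage_matrix`.
#' @param sumstats discovery `sumstat_table`.
#' @param p_max,r2_max,window_kb,apoe_region pipeline parameters.
#' @return list: `weights` (final, APOE-excluded), `clumped` (pre-exclusion,
#'   used for pathway partitioning and PCs), `matched`, `qc_keep`, `counts`.
#' @export
build_weights <- function(dosages, sumstats, p_max = 0.5, r2_max = 0.1,
                          window_kb = 1000,
                          apoe_region = apoe_region_default()) {
  qc_keep <- variant_qc(dosages)
  tv <- dosages$variants[dosages$variants$id %in% qc_keep, , drop = FALSE]
  matched <- match_alleles(tv, sumstats)
  sel <- select_by_p(matched, p_max)
  clumped <- ld_clump(sel, dosages, r2_max = r2_max, window_kb = window_kb)
  weights <- exclude_region(clumped, apoe_region)
  counts <- c(n_variants = nrow(dosages$variants),
              n_qc = length(qc_keep), n_matched = nrow(matched),
              n_p_selected = nrow(sel), n_clumped = nrow(clumped),
              n_final = nrow(weights))
  list(weights = weights, clumped = clumped, matched = matched,
       qc_keep = qc_keep, counts = counts,
       params = list(p_max = p_max, r2_max = r2_max, window_kb = window_kb,
                     apoe_region = parse_region(apoe_region)))
}

# score one weight table, adjust for covariates, standardize; NA column if
# the table is empty
score_column <- function(dosages, wtab, covariates) {
  if (is.null(wtab) || !nrow(wtab))
    return(rep(NA_real_, nrow(dosages$dosages)))
  adjust_standardize(compute_raw_prs(dosages, wtab), covariates)
}

#' Assemble the per-subject score set
#'
#' Computes the raw and PC-adjusted standardized genome-wide PRS, the APOE
#' epsilon counts, and (optionally) pathway scores with and without the
#' APOE region plus the whole-genome-minus-pathways complement. Genome-wide
#' scores are adjusted for the principal components; pathway scores
#' additionally for age and sex, then standardized.
#'
#' @param dosages target `dosage_matrix`.
#' @param built output of [build_weights()].
#' @param sex,age per-sample covariate vectors (row order of `dosages`).
#' @param n_pcs number of principal components (default 8), computed on the
#'   final clumped variant set.
#' @param annotation optional list(genes, sets) for pathway scores.
#' @param apoe_region region for the no-APOE pathway variants.
#' @return data.frame (class `score_set`): IID, PRS_RAW, PRS_STD, EPS2,
#'   EPS4, SEX, AGE and pathway columns `PW_*` / `PW_*_noapoe` /
#'   `PW_complement`; PC matrix in attribute `pcs`.
#' @export
build_scores <- function(dosages, built, sex, age, n_pcs = 8L,
                         annotation = NULL,
                         apoe_region = apoe_region_default()) {
  stopifnot(inherits(dosages, "dosage_matrix"))
  raw <- compute_raw_prs(dosages, built$weights)
  pcs <- compute_pcs(dosages, k = n_pcs, snp_ids = built$weights$SNP)
  std <- adjust_standardize(raw, pcs)
  apoe <- apoe_allele_counts(dosages)
  out <- data.frame(IID = dosages$samples$iid, PRS_RAW = raw,
                    PRS_STD = std, EPS2 = apoe$eps2, EPS4 = apoe$eps4,
                    SEX = sex, AGE = age, stringsAsFactors = FALSE,
                    row.names = NULL)
  if (!is.null(annotation)) {
    covs <- cbind(pcs, AGE = age, SEX = sex)
    part <- pathway_partition(built$clumped, annotation$sets,
                              annotation$genes, drop_apoe = FALSE)
    part_no <- pathway_partition(built$clumped, annotation$sets,
                                 annotation$genes, drop_apoe = TRUE,
                                 apoe_region = apoe_region)
    for (nm in names(part$pathways)) {
      out[[paste0("PW_", nm)]] <- score_column(dosages, part$pathways[[nm]],
                                               covs)
      out[[paste0("PW_", nm, "_noapoe")]] <-
        score_column(dosages, part_no$pathways[[nm]], covs)
    }
    out$PW_complement <- score_column(dosages, part$complement, covs)
  }
  attr(out, "pcs") <- pcs
  class(out) <- c("score_set", "data.frame")
  out
}

#' Run the full analysis pipeline on a synthetic configuration
#'
#' Generates the cohorts, computes discovery summary statistics, builds the
#' weight tables and score set, classifies trajectories, forms the four
#' contrasts (AD vs controls, MCI vs controls, amyloid-positive vs
#' -negative, and MCI->AD conversion among amyloid-positive baseline-MCI
#' subjects), runs the three-model battery on each, optionally the pathway
#' batteries and the overlap-correction simulation, and optionally writes
#' the report bundle.
#'
#' @param config a [sim_config()].
#' @param out_dir optional output directory for the report bundle.
#' @param n_pcs principal components (default 8).
#' @param extremes_k SD cutoff for the extremes re-run (default 1.5).
#' @param pathways run the pathway batteries.
#' @param overlap_c optional overlap SD multiplier; when non-NULL the
#'   overlap-correction simulation is run on the AD contrast with
#'   `n_overlap_sims` replicates.
#' @param n_overlap_sims replicates for the overlap simulation.
#' @param apoe_override optional fixed `c(beta_eps2, beta_eps4)`.
#' @return report bundle (class `prs_report`): contrasts, batteries,
#'   pathway tables, weight-table counts, score set, manifest.
#' @export
run_pipeline <- function(config = sim_config(), out_dir = NULL, n_pcs = 8L,
                         extremes_k = 1.5, pathways = TRUE,
                         overlap_c = NULL, n_overlap_sims = 200L,
                         apoe_override = NULL) {
  stopifnot(inherits(config, "sim_config"))
  dm <- gen_ld_genotypes(config)
  eff <- plant_effects(dm$variants, config)
  sim <- gen_two_stage_phenotypes(dm, eff, config)
  di <- discovery_indices(sim, config)
  ss <- gen_discovery_sumstats(dm$dosages[di, , drop = FALSE],
                               sim$truth$disease[di], dm$variants)
  t_idx <- which(sim$truth$role == "target")
  dm_t <- subset_dosages(dm, rows = t_idx)
  visits_t <- sim$visits[sim$visits$IID %in% dm_t$samples$iid, , drop = FALSE]
  labels <- suppressWarnings(classify_trajectory(visits_t))
  amyloid <- assign_amyloid(visits_t)
  contrasts <- build_contrasts(labels, amyloid)
  built <- build_weights(dm_t, ss)
  annotation <- if (pathways) gen_gene_annotation(dm$variants,
                                                  seed = config$seed) else NULL
  truth_t <- sim$truth[t_idx, , drop = FALSE]
  scores <- build_scores(dm_t, built, sex = truth_t$sex, age = truth_t$age,
                         n_pcs = n_pcs, annotation = annotation)
  apoe <- apoe_allele_counts(dm_t)
  # the battery models carry eps2/eps4 as free coefficients, so a sparse
  # epsilon cell in the AD arm only degrades this summary, not the models
  aw <- tryCatch(
    estimate_apoe_weights(contrasts$ad_vs_control, apoe,
                          override = apoe_override),
    error = function(e) list(beta_eps2 = NA_real_, beta_eps4 = NA_real_,
                             se = c(NA_real_, NA_real_), n = NA_integer_,
                             source = conditionMessage(e)))
  batteries <- lapply(contrasts, function(ct)
    run_model_battery(ct, scores, extremes_k = extremes_k))
  pathway_results <- NULL
  if (pathways) {
    cols <- grep("^PW_", names(scores), value = TRUE)
    cols <- cols[colSums(!is.na(scores[cols])) > 0]
    pathway_results <- lapply(contrasts, function(ct)
      battery_pathways(ct, scores, cols))
  }
  overlap <- NULL
  if (!is.null(overlap_c)) {
    overlap <- simulate_corrected_auc(
      built$matched, dm_t, contrasts$ad_vs_control,
      scores[, c("IID", "EPS2", "EPS4", "SEX", "AGE")], c = overlap_c,
      n_sims = n_overlap_sims, seed = config$seed,
      pcs = attr(scores, "pcs"))
  }
  manifest <- list(seed = config$seed, parameters = unclass(config),
                   counts = as.list(built$counts),
                   apoe_weights = aw[c("beta_eps2", "beta_eps4", "source")],
                   contrast_n = lapply(contrasts, attr, "n"),
                   label_convention = "MCI->AD converters labelled MCI")
  report <- structure(list(config = config, contrasts = contrasts,
                           labels = labels, amyloid = amyloid,
                           scores = scores, built = built,
                           apoe_weights = aw, batteries = batteries,
                           pathways = pathway_results, overlap = overlap,
                           truth = sim$truth, manifest = manifest),
                      class = "prs_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @exportS3Method base::print
print.prs_report <- function(x, ...) {
  cat("PRS analysis report (synthetic cohort)\n")
  cat(sprintf("  variants: %d genotyped -> %d scored\n",
              x$manifest$counts$n_variants, x$manifest$counts$n_final))
  for (nm in names(x$batteries)) {
    b <- x$batteries[[nm]]
    cat(sprintf("  %-20s n=%d/%d  AUC(apoe)=%.2f AUC(full)=%.2f  LRT p=%.3g\n",
                nm, b$n["case"], b$n["control"],
                b$aucs$auc_cov[b$aucs$model == "apoe"],
                b$aucs$auc_cov[b$aucs$model == "full"],
                b$lrt_full_vs_apoe$p))
  }
  invisible(x)
}

#' Write the report bundle to disk
#'
#' Emits scores.tsv, labels.tsv, battery.json (all contrasts), pathway
#' tables (when present) and manifest.json into `out_dir`.
#'
#' @param report a `prs_report`.
#' @param out_dir output directory (created if needed).
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(report$scores, file.path(out_dir, "scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  lab <- merge(report$labels, report$amyloid[, c("IID", "status")],
               by = "IID")
  names(lab)[names(lab) == "status"] <- "AMYLOID"
  utils::write.table(lab, file.path(out_dir, "labels.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  bat <- lapply(report$batteries, function(b)
    list(n = as.list(b$n), aucs = b$aucs, lrt = b$lrt_full_vs_apoe,
         extremes = b$extremes))
  jsonlite::write_json(bat, file.path(out_dir, "battery.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(report$pathways))
    jsonlite::write_json(report$pathways,
                         file.path(out_dir, "pathways.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows",
                         pretty = TRUE)
  jsonlite::write_json(report$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Synthesize an on-disk dataset
#'
#' Generates the cohorts from a [sim_config()] and writes every pipeline
#' input: target and discovery VCFs (GT hard calls), discovery summary
#' statistics TSV, cohort visit TSV, gene intervals BED, gene sets GMT and
#' a manifest recording the seed and all parameters.
#'
#' @param config a [sim_config()].
#' @param dir output directory.
#' @return invisible list of file paths.
#' @export
synthesize_dataset <- function(config, dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dm <- gen_ld_genotypes(config)
  eff <- plant_effects(dm$variants, config)
  sim <- gen_two_stage_phenotypes(dm, eff, config)
  di <- discovery_indices(sim, config)
  ss <- gen_discovery_sumstats(dm$dosages[di, , drop = FALSE],
                               sim$truth$disease[di], dm$variants)
  ann <- gen_gene_annotation(dm$variants, seed = config$seed)
  t_idx <- which(sim$truth$role == "target")
  paths <- list(
    vcf_target = file.path(dir, "target.vcf"),
    vcf_discovery = file.path(dir, "discovery.vcf"),
    sumstats = file.path(dir, "sumstats.tsv"),
    cohort = file.path(dir, "cohort.tsv"),
    genes = file.path(dir, "genes.bed"),
    gene_sets = file.path(dir, "gene_sets.gmt"),
    manifest = file.path(dir, "manifest.json"))
  write_vcf(subset_dosages(dm, rows = t_idx), paths$vcf_target)
  write_vcf(subset_dosages(dm, rows = di), paths$vcf_discovery)
  write_sumstats(ss, paths$sumstats)
  visits_t <- sim$visits[sim$visits$IID %in% dm$samples$iid[t_idx], ,
                         drop = FALSE]
  write_cohort(visits_t, paths$cohort)
  write_bed(ann$genes, paths$genes)
  write_gmt(ann$sets, paths$gene_sets)
  jsonlite::write_json(list(seed = config$seed,
                            parameters = unclass(config),
                            files = lapply(paths, basename)),
                       paths$manifest, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(paths)
}
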