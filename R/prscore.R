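# Polygenic score construction: variant QC, allele harmonization against
# discovery summary statistics, p-value selection, greedy LD clumping, APOE
# epsilon2/epsilon4 handling, principal components, covariate adjustment and
# standardization, and pathway partitioning. Pipeline order is fixed:
# QC -> match -> p-select -> clump -> (region-exclude) -> score.

dosage_parts <- function(dosages, variants = NULL) {
  if (inherits(dosages, "dosage_matrix"))
    list(G = dosages$dosages, variants = dosages$variants)
  else {
    if (is.null(variants)) stop("variant metadata required with a bare matrix")
    list(G = dosages, variants = variants)
  }
}

#' Exact Hardy-Weinberg equilibrium test p-value
#'
#' Two-sided exact test on genotype counts: the p-value is the total
#' probability, under the conditional distribution of heterozygote count
#' given allele counts, of all outcomes no more probable than the observed
#' one.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts.
#' @return exact p-value in (0, 1].
#' @export
hwe_exact_p <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  if (n == 0L) return(1)
  n1 <- 2L * n_hom_alt + n_het           # alt allele count
  hets <- seq(n1 %% 2L, min(n1, 2L * n - n1), by = 2L)
  # log P(het = h | n, n1) up to a constant
  lp <- vapply(hets, function(h) {
    haa <- (n1 - h) / 2
    hrr <- n - haa - h
    h * log(2) - lfactorial(haa) - lfactorial(h) - lfactorial(hrr)
  }, numeric(1))
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  obs <- p[hets == n_het]
  sum(p[p <= obs + 1e-12])
}

#' Variant quality control
#'
#' Removes variants with genotype missingness > `miss_max` (0.02), exact
#' Hardy-Weinberg p-value < `hwe_min` (1e-6) computed in the full sample,
#' or minor allele frequency < `maf_min` (0.01, computed among non-missing
#' calls; monomorphic variants always fail).
#'
#' @param dosages a `dosage_matrix` or samples-x-variants matrix.
#' @param variants variant table when `dosages` is a bare matrix.
#' @param miss_max,hwe_min,maf_min filter thresholds.
#' @return character vector of retained variant ids, with a `counts`
#'   attribute giving removals per filter.
#' @export
variant_qc <- function(dosages, variants = NULL, miss_max = 0.02,
                       hwe_min = 1e-6, maf_min = 0.01) {
  dp <- dosage_parts(dosages, variants)
  G <- dp$G
  n <- nrow(G)
  miss <- colSums(is.na(G)) / n
  frq <- colMeans(G, na.rm = TRUE) / 2
  maf <- pmin(frq, 1 - frq)
  maf[is.nan(maf)] <- 0
  hwe <- vapply(seq_len(ncol(G)), function(j) {
    g <- G[, j]
    g <- g[!is.na(g)]
    hwe_exact_p(sum(g == 0L), sum(g == 1L), sum(g == 2L))
  }, numeric(1))
  fail_miss <- miss > miss_max
  fail_hwe <- hwe < hwe_min
  fail_maf <- maf < maf_min
  keep <- !(fail_miss | fail_hwe | fail_maf)
  out <- dp$variants$id[keep]
  attr(out, "counts") <- c(n_in = ncol(G), fail_missingness = sum(fail_miss),
                           fail_hwe = sum(fail_hwe), fail_maf = sum(fail_maf),
                           n_out = sum(keep))
  out
}

ALLELE_COMP <- c(A = "T", T = "A", C = "G", G = "C")

#' Harmonize summary-statistic alleles to the target's counted allele
#'
#' Variants are matched on chromosome:position. An exact allele match keeps
#' the discovery beta; swapped alleles negate it; a strand flip (allele
#' complements) is resolved in either orientation; palindromic A/T and C/G
#' variants are dropped (strand unresolvable without frequencies), as are
#' position matches with irreconcilable alleles. All drops are counted.
#'
#' @param target_variants variant table (id, chrom, pos, a1 = counted, a2).
#' @param sumstats a `sumstat_table`.
#' @param drop_palindromic drop A/T and C/G variants (default TRUE).
#' @return weight table (class `weight_table`): SNP, CHR, BP, A1 (target
#'   counted allele), A2, BETA (aligned), SE, P; attribute `counts`.
#' @export
match_alleles <- function(target_variants, sumstats,
                          drop_palindromic = TRUE) {
  tv <- target_variants
  key_t <- paste(tv$chrom, tv$pos, sep = ":")
  key_s <- paste(sumstats$CHR, sumstats$BP, sep = ":")
  i <- match(key_t, key_s)
  hit <- !is.na(i)
  tv <- tv[hit, , drop = FALSE]
  ss <- sumstats[i[hit], , drop = FALSE]
  palin <- tv$a1 == unname(ALLELE_COMP[tv$a2])
  n_palin <- 0L
  if (drop_palindromic) {
    n_palin <- sum(palin)
    tv <- tv[!palin, , drop = FALSE]
    ss <- ss[!palin, , drop = FALSE]
  }
  exact <- ss$A1 == tv$a1 & ss$A2 == tv$a2
  swap <- ss$A1 == tv$a2 & ss$A2 == tv$a1
  flip <- unname(ALLELE_COMP[ss$A1]) == tv$a1 &
    unname(ALLELE_COMP[ss$A2]) == tv$a2
  flipswap <- unname(ALLELE_COMP[ss$A1]) == tv$a2 &
    unname(ALLELE_COMP[ss$A2]) == tv$a1
  sign <- rep(NA_real_, nrow(tv))
  sign[exact | (!exact & flip)] <- 1
  sign[(swap & !exact) | (flipswap & !exact & !flip)] <- -1
  ok <- !is.na(sign)
  out <- data.frame(SNP = tv$id[ok], CHR = tv$chrom[ok], BP = tv$pos[ok],
                    A1 = tv$a1[ok], A2 = tv$a2[ok],
                    BETA = ss$BETA[ok] * sign[ok], SE = ss$SE[ok],
                    P = ss$P[ok], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "counts") <- c(n_target = length(key_t),
                           n_position_matched = sum(hit),
                           n_palindromic_dropped = n_palin,
                           n_allele_mismatch = sum(!ok),
                           n_swapped = sum(ok & sign < 0),
                           n_out = nrow(out))
  class(out) <- c("weight_table", "data.frame")
  out
}

#' Select variants by discovery p-value
#'
#' Retains rows with `P <= p_max` (boundary inclusive; the 0.5 default is
#' the threshold with the best reported AD prediction accuracy).
#'
#' @param weights a `weight_table`.
#' @param p_max inclusive p-value ceiling.
#' @export
select_by_p <- function(weights, p_max = 0.5) {
  out <- weights[weights$P <= p_max, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("weight_table", "data.frame")
  out
}

#' Greedy LD clumping, keeping the most-associated variant per neighborhood
#'
#' Repeatedly takes the unclaimed variant with the smallest discovery
#' p-value (ties broken by chromosome then position) as an index, and
#' removes every unclaimed variant on the same chromosome within
#' `window_kb` kilobases whose squared Pearson dosage correlation with the
#' index is `>= r2_max`. Only index variants survive. r-squared is computed
#' in the target dosages (no external reference panel).
#'
#' @param weights a `weight_table` (any row order).
#' @param dosages target `dosage_matrix` (or matrix with variant id
#'   colnames) supplying dosages for r-squared.
#' @param r2_max clumping r-squared threshold in (0, 1].
#' @param window_kb window half-width in kb (> 0); boundary inclusive.
#' @return the retained `weight_table`, ordered by (CHR, BP).
#' @export
ld_clump <- function(weights, dosages, r2_max = 0.1, window_kb = 1000) {
  if (window_kb <= 0) stop("window_kb must be positive")
  if (r2_max <= 0 || r2_max > 1) stop("r2_max must lie in (0, 1]")
  G <- if (inherits(dosages, "dosage_matrix")) dosages$dosages else dosages
  if (!nrow(weights)) return(weights)
  if (!all(weights$SNP %in% colnames(G)))
    stop("dosages missing for some weight-table variants")
  ord <- order(weights$P, weights$CHR, weights$BP)
  alive <- rep(TRUE, nrow(weights))
  keep <- logical(nrow(weights))
  win <- window_kb * 1000
  for (i in ord) {
    if (!alive[i]) next
    keep[i] <- TRUE
    alive[i] <- FALSE
    near <- which(alive & weights$CHR == weights$CHR[i] &
                    abs(weights$BP - weights$BP[i]) <= win)
    if (!length(near)) next
    gi <- G[, weights$SNP[i]]
    r2 <- suppressWarnings(
      as.numeric(stats::cor(gi, G[, weights$SNP[near], drop = FALSE],
                            use = "pairwise.complete.obs"))^2)
    drop <- near[!is.na(r2) & r2 >= r2_max]
    alive[drop] <- FALSE
  }
  out <- weights[keep, , drop = FALSE]
  out <- out[order(out$CHR, out$BP), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("weight_table", "data.frame")
  out
}

#' Exclude variants inside a genomic region
#'
#' Default use: removing the APOE region (chr19:44,400,000-46,500,000,
#' 1-based closed) from the polygenic score so the APOE terms and the PRS
#' share no variants.
#'
#' @param weights a `weight_table` (or any data.frame with CHR/BP).
#' @param region region spec for [parse_region()].
#' @export
exclude_region <- function(weights, region = apoe_region_default()) {
  r <- parse_region(region)
  drop <- weights$CHR == r$chrom & weights$BP >= r$start & weights$BP <= r$end
  out <- weights[!drop, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("weight_table", "data.frame")
  attr(out, "n_excluded") <- sum(drop)
  out
}

#' APOE epsilon-allele counts from the two defining SNPs
#'
#' Unphased genotypes at the rs429358-like (epsilon4, alt C) and
#' rs7412-like (epsilon2, alt T) sites map to allele counts via the
#' standard diplotype table: eps4 = C-allele count at the first site,
#' eps2 = T-allele count at the second. The doubly heterozygous diplotype
#' is resolved as epsilon2/epsilon4 (the epsilon1/epsilon3 phase is assumed
#' absent). Counts summing above two are invalid and returned missing.
#'
#' @param dosages `dosage_matrix` containing both sites.
#' @param e4_id,e2_id variant ids of the epsilon4- and epsilon2-defining
#'   sites; defaults locate the generator's `apoe_slot` tags.
#' @return data.frame: IID, eps2, eps4 (NA when either genotype is missing).
#' @export
apoe_allele_counts <- function(dosages, e4_id = NULL, e2_id = NULL) {
  stopifnot(inherits(dosages, "dosage_matrix"))
  v <- dosages$variants
  if (is.null(e4_id)) e4_id <- v$id[match("e4_site", v$apoe_slot)]
  if (is.null(e2_id)) e2_id <- v$id[match("e2_site", v$apoe_slot)]
  if (is.na(e4_id) || is.na(e2_id) ||
      !all(c(e4_id, e2_id) %in% colnames(dosages$dosages)))
    stop("both APOE-defining variants must be present")
  d4 <- dosages$dosages[, e4_id]
  d2 <- dosages$dosages[, e2_id]
  bad <- !is.na(d4) & !is.na(d2) & (d4 + d2 > 2L)
  if (any(bad)) {
    warning(sum(bad), " subject(s) with impossible epsilon diplotypes set to missing")
    d4[bad] <- NA_integer_; d2[bad] <- NA_integer_
  }
  miss <- is.na(d4) | is.na(d2)
  d4[miss] <- NA_integer_; d2[miss] <- NA_integer_
  data.frame(IID = dosages$samples$iid, eps2 = d2, eps4 = d4,
             stringsAsFactors = FALSE)
}

#' Estimate APOE epsilon2/epsilon4 effect sizes in the target data
#'
#' Joint logistic regression of case status on eps2 and eps4 counts; the
#' two coefficients form the APOE term of the full PRS,
#' `apoe_score = beta_eps2 * eps2 + beta_eps4 * eps4`. Fixed reference
#' magnitudes (e.g. -1.04 / +1.55 as estimated in ADNI) can be supplied via
#' `override` when no suitable contrast exists.
#'
#' @param contrast data.frame (IID, case) - typically AD vs controls.
#' @param apoe output of [apoe_allele_counts()].
#' @param override optional fixed `c(beta_eps2, beta_eps4)`.
#' @return list: beta_eps2, beta_eps4, se (length 2), n.
#' @export
estimate_apoe_weights <- function(contrast, apoe, override = NULL) {
  if (!is.null(override)) {
    stopifnot(length(override) == 2L)
    return(list(beta_eps2 = override[[1]], beta_eps4 = override[[2]],
                se = c(NA_real_, NA_real_), n = NA_integer_,
                source = "override"))
  }
  d <- merge(contrast, apoe, by = "IID")
  d <- d[stats::complete.cases(d[, c("case", "eps2", "eps4")]), ]
  if (!sum(d$case) || !sum(!d$case)) stop("both arms must be non-empty")
  fit <- suppressWarnings(
    stats::glm(case ~ eps2 + eps4, family = stats::binomial(), data = d))
  co <- stats::coef(fit)
  if (!fit$converged || any(abs(co[-1]) > 12, na.rm = TRUE))
    stop("(quasi-)separation in the APOE fit; supply a fixed override ",
         "(e.g. the published -1.04 / +1.55) or a penalized estimate")
  se <- sqrt(diag(stats::vcov(fit)))[c("eps2", "eps4")]
  list(beta_eps2 = unname(co["eps2"]), beta_eps4 = unname(co["eps4"]),
       se = unname(se), n = nrow(d), source = "estimated")
}

#' Raw polygenic score: weighted allele-dosage sum
#'
#' `score_i = sum_j weight_j * dosage_ij` over the weight-table variants,
#' with missing dosages mean-imputed per variant at this step only (QC sees
#' true missingness).
#'
#' @param dosages `dosage_matrix` (or bare matrix with id colnames).
#' @param weights a `weight_table` aligned to the target counted alleles.
#' @return named numeric vector of scores (names = sample ids).
#' @export
compute_raw_prs <- function(dosages, weights) {
  G <- if (inherits(dosages, "dosage_matrix")) dosages$dosages else dosages
  use <- intersect(weights$SNP, colnames(G))
  if (!length(use)) stop("no overlapping variants between weights and dosages")
  W <- weights$BETA[match(use, weights$SNP)]
  X <- G[, use, drop = FALSE]
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    na <- which(is.na(X), arr.ind = TRUE)
    X[na] <- mu[na[, 2]]
  }
  drop(X %*% W)
}

#' Top principal components of the standardized genotype matrix
#'
#' Columns are centered by twice the observed allele frequency and scaled
#' by `sqrt(2 f (1 - f))`, then the top `k` left singular vectors are
#' returned (orthonormal columns). Computed once on the LD-clumped
#' genome-wide variants and reused for every score.
#'
#' @param dosages `dosage_matrix` or matrix.
#' @param k number of components (default 8).
#' @param snp_ids optional subset of variant ids (e.g. the clumped set).
#' @return samples x k matrix with orthonormal columns.
#' @export
compute_pcs <- function(dosages, k = 8L, snp_ids = NULL) {
  G <- if (inherits(dosages, "dosage_matrix")) dosages$dosages else dosages
  if (!is.null(snp_ids)) G <- G[, intersect(snp_ids, colnames(G)), drop = FALSE]
  storage.mode(G) <- "double"
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    na <- which(is.na(G), arr.ind = TRUE)
    G[na] <- mu[na[, 2]]
  }
  f <- colMeans(G) / 2
  keep <- f > 0 & f < 1
  G <- G[, keep, drop = FALSE]
  f <- f[keep]
  Z <- sweep(sweep(G, 2L, 2 * f), 2L, sqrt(2 * f * (1 - f)), "/")
  if (k > min(dim(Z))) stop("k exceeds the rank of the genotype matrix")
  sv <- svd(Z, nu = k, nv = 0)
  if (sv$d[k] < sqrt(.Machine$double.eps) * sv$d[1])
    stop("k exceeds the numerical rank of the genotype matrix")
  pcs <- sv$u
  colnames(pcs) <- paste0("PC", seq_len(k))
  rownames(pcs) <- rownames(G)
  pcs
}

#' Adjust a score for covariates and standardize
#'
#' Ordinary least-squares residuals of the score on the covariates (with
#' intercept), then z-scored to mean 0 / SD 1.
#'
#' @param scores numeric vector.
#' @param covariates matrix/data.frame of covariates (e.g. 8 PCs, optionally
#'   age and sex for pathway scores); may be NULL for plain standardization.
#' @return standardized numeric vector (names preserved).
#' @export
adjust_standardize <- function(scores, covariates = NULL) {
  if (is.null(covariates)) {
    r <- scores - mean(scores)
  } else {
    X <- cbind(1, as.matrix(covariates))
    if (qr(X)$rank < ncol(X)) stop("covariate matrix is rank deficient")
    r <- stats::lm.fit(X, scores)$residuals
  }
  s <- stats::sd(r)
  if (s == 0) stop("score has zero residual variance")
  out <- (r - mean(r)) / s
  names(out) <- names(scores)
  out
}

#' Partition a weight table into pathway-specific tables plus a complement
#'
#' A variant belongs to a pathway iff its position lies within any member
#' gene's interval (1-based closed; optional `flank_bp` on each side). The
#' complement holds every retained weight in no pathway. With
#' `drop_apoe = TRUE` the APOE region is excluded from each pathway table
#' first. Gene-set members absent from the gene map are counted in the
#' `unmapped` attribute.
#'
#' @param weights the retained (clumped) `weight_table`.
#' @param sets named list of gene-id vectors (GMT content).
#' @param genes gene map data.frame (chrom, start, end, gene; 1-based
#'   closed).
#' @param drop_apoe apply [exclude_region()] to each pathway table.
#' @param apoe_region region passed to [exclude_region()].
#' @param flank_bp symmetric flank added to gene intervals (default 0).
#' @return list: `pathways` (named list of weight tables), `complement`.
#' @export
pathway_partition <- function(weights, sets, genes, drop_apoe = FALSE,
                              apoe_region = apoe_region_default(),
                              flank_bp = 0) {
  need_cols(genes, c("chrom", "start", "end", "gene"), "gene map")
  in_any <- rep(FALSE, nrow(weights))
  unmapped <- character(0)
  pathways <- vector("list", length(sets))
  names(pathways) <- names(sets)
  for (nm in names(sets)) {
    gm <- genes[genes$gene %in% sets[[nm]], , drop = FALSE]
    unmapped <- c(unmapped, setdiff(sets[[nm]], genes$gene))
    member <- rep(FALSE, nrow(weights))
    for (g in seq_len(nrow(gm))) {
      member <- member | (weights$CHR == gm$chrom[g] &
                            weights$BP >= gm$start[g] - flank_bp &
                            weights$BP <= gm$end[g] + flank_bp)
    }
    in_any <- in_any | member
    tab <- weights[member, , drop = FALSE]
    rownames(tab) <- NULL
    class(tab) <- c("weight_table", "data.frame")
    if (drop_apoe) tab <- exclude_region(tab, apoe_region)
    pathways[[nm]] <- tab
  }
  complement <- weights[!in_any, , drop = FALSE]
  rownames(complement) <- NULL
  class(complement) <- c("weight_table", "data.frame")
  out <- list(pathways = pathways, complement = complement)
  attr(out, "unmapped") <- unique(unmapped)
  out
}
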