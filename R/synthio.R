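# Synthetic cohort generator: LD-blocked genotypes with a two-SNP APOE-like
# locus, a two-stage liability phenotype (APOE drives amyloid positivity, a
# polygenic background drives MCI->AD conversion), discovery GWAS summary
# statistics, and gene interval / gene set annotation.

# run expr under a temporary seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Simulation configuration
#'
#' Bundles every free parameter of the synthetic cohort generator. The
#' defaults define the package's reference study conditions: a target cohort
#' of 770 subjects aged 55-90 (the scale of a longitudinal imaging cohort), a
#' larger disjoint discovery cohort supplying GWAS summary statistics, 20
#' independent LD blocks of 25 SNPs, and a two-stage liability model in which
#' only the two-SNP APOE-like locus moves amyloid liability
#' (`w_amyloid_apoe`) while a polygenic background of `n_causal` variants
#' moves conversion liability (`w_convert_poly`, the standard deviation of
#' the polygenic conversion component on the liability scale).
#'
#' @param seed integer RNG seed; every generator is a pure function of the
#'   config including this seed.
#' @param n_target,n_discovery target / discovery cohort sizes.
#' @param n_overlap_cases,n_overlap_controls number of target disease cases /
#'   non-cases also included in the discovery GWAS sample (0 = disjoint
#'   cohorts).
#' @param n_blocks,snps_per_block LD-block layout; one block (`apoe_block`)
#'   is placed on chromosome 19 at 44.9 Mb and carries the APOE-like locus.
#' @param ld_decay in \[0,1\]; adjacent-variant haplotype correlation is
#'   `1 - ld_decay` (1 = full independence).
#' @param maf_range block minor-allele frequencies are drawn uniformly here.
#' @param apoe_block index of the APOE-like block.
#' @param apoe_hap_freqs named frequencies of the epsilon2/3/4 haplotype
#'   analogues at the two-SNP locus.
#' @param w_amyloid_apoe,w_convert_apoe,w_convert_poly liability weights (SD
#'   units of the corresponding genetic component).
#' @param amyloid_threshold_quantile amyloid-positivity threshold quantile of
#'   the amyloid liability.
#' @param convert_threshold_quantile conversion threshold quantile of the
#'   conversion liability among amyloid-positive subjects.
#' @param n_causal number of causal background variants (outside the APOE
#'   block).
#' @param n_visits number of longitudinal visits per subject.
#' @param frac_prevalent_ad fraction of converters already AD at baseline
#'   (stable AD trajectory).
#' @param frac_pos_nonconv_mci fraction of amyloid-positive non-converters
#'   labelled stable MCI (remainder stable control).
#' @param frac_neg_mci fraction of amyloid-negative subjects labelled stable
#'   MCI (non-AD cognitive impairment; remainder stable control).
#' @param flip_cn_mci,flip_mci_cn,flip_ad_mci post-hoc label-flip rates
#'   producing control->MCI, MCI->control and AD->MCI trajectories.
#' @param suvr_missing fraction of subjects with no amyloid PET (SUVR `NA`).
#' @param two_pop,fst optional two-population toggle (Balding-Nichols
#'   frequency divergence), used for principal-component tests only.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_target = 770L,
                       n_discovery = 2500L,
                       n_overlap_cases = 0L,
                       n_overlap_controls = 0L,
                       n_blocks = 20L,
                       snps_per_block = 25L,
                       ld_decay = 0.1,
                       maf_range = c(0.05, 0.5),
                       apoe_block = n_blocks,
                       apoe_hap_freqs = c(e2 = 0.08, e3 = 0.77, e4 = 0.15),
                       w_amyloid_apoe = 1.0,
                       w_convert_apoe = 0.3,
                       w_convert_poly = 1.2,
                       amyloid_threshold_quantile = 0.55,
                       convert_threshold_quantile = 0.5,
                       n_causal = 150L,
                       n_visits = 4L,
                       frac_prevalent_ad = 0.4,
                       frac_pos_nonconv_mci = 0.7,
                       frac_neg_mci = 0.4,
                       flip_cn_mci = 0.02,
                       flip_mci_cn = 0.01,
                       flip_ad_mci = 0.01,
                       suvr_missing = 0.1,
                       two_pop = FALSE,
                       fst = 0.1) {
  cfg <- list(seed = as.integer(seed), n_target = as.integer(n_target),
              n_discovery = as.integer(n_discovery),
              n_overlap_cases = as.integer(n_overlap_cases),
              n_overlap_controls = as.integer(n_overlap_controls),
              n_blocks = as.integer(n_blocks),
              snps_per_block = as.integer(snps_per_block),
              ld_decay = ld_decay, maf_range = maf_range,
              apoe_block = as.integer(apoe_block),
              apoe_hap_freqs = apoe_hap_freqs,
              w_amyloid_apoe = w_amyloid_apoe,
              w_convert_apoe = w_convert_apoe,
              w_convert_poly = w_convert_poly,
              amyloid_threshold_quantile = amyloid_threshold_quantile,
              convert_threshold_quantile = convert_threshold_quantile,
              n_causal = as.integer(n_causal), n_visits = as.integer(n_visits),
              frac_prevalent_ad = frac_prevalent_ad,
              frac_pos_nonconv_mci = frac_pos_nonconv_mci,
              frac_neg_mci = frac_neg_mci,
              flip_cn_mci = flip_cn_mci, flip_mci_cn = flip_mci_cn,
              flip_ad_mci = flip_ad_mci, suvr_missing = suvr_missing,
              two_pop = isTRUE(two_pop), fst = fst)
  if (cfg$n_target <= 0L || cfg$n_discovery <= 0L || cfg$n_blocks <= 0L ||
      cfg$snps_per_block <= 0L || cfg$n_visits <= 0L)
    stop("counts must be positive")
  if (cfg$n_overlap_cases < 0L || cfg$n_overlap_controls < 0L ||
      cfg$n_overlap_cases + cfg$n_overlap_controls > cfg$n_discovery)
    stop("overlap counts must be non-negative and sum to <= n_discovery")
  if (cfg$ld_decay < 0 || cfg$ld_decay > 1) stop("ld_decay must lie in [0,1]")
  if (length(cfg$maf_range) != 2L || cfg$maf_range[1] > cfg$maf_range[2] ||
      cfg$maf_range[1] <= 0 || cfg$maf_range[2] > 0.5)
    stop("maf_range must be an ordered pair inside (0, 0.5]")
  if (cfg$apoe_block < 1L || cfg$apoe_block > cfg$n_blocks)
    stop("apoe_block out of range")
  if (cfg$snps_per_block < 2L) stop("the APOE block needs >= 2 variant slots")
  qs <- c(cfg$amyloid_threshold_quantile, cfg$convert_threshold_quantile)
  if (any(qs <= 0 | qs >= 1)) stop("threshold quantiles must lie in (0,1)")
  ws <- c(cfg$w_amyloid_apoe, cfg$w_convert_apoe, cfg$w_convert_poly)
  if (any(!is.finite(ws))) stop("liability weights must be finite")
  if (cfg$n_causal < 0L ||
      cfg$n_causal > (cfg$n_blocks - 1L) * cfg$snps_per_block)
    stop("n_causal exceeds the number of non-APOE variants")
  if (abs(sum(cfg$apoe_hap_freqs) - 1) > 1e-8)
    stop("apoe_hap_freqs must sum to 1")
  structure(cfg, class = "sim_config")
}

# block layout: APOE block sits on chr19 inside 44.4-46.5 Mb, all others on
# chr1 separated by ~3 Mb so 1,000 kb pruning windows never span blocks
block_layout <- function(cfg) {
  spacing <- 2000L
  idx <- seq_len(cfg$n_blocks)
  chrom <- ifelse(idx == cfg$apoe_block, "19", "1")
  ord <- cumsum(idx != cfg$apoe_block)
  start <- ifelse(idx == cfg$apoe_block, 44900000L,
                  1000000L + (ord - 1L) * 3000000L)
  data.frame(block = idx, chrom = chrom, start = start, spacing = spacing,
             stringsAsFactors = FALSE)
}

# non-palindromic allele pairs only, so harmonization never drops simulated
# variants for strand ambiguity
allele_pairs <- function(n) {
  pairs <- rbind(c("A", "G"), c("A", "C"), c("T", "G"), c("T", "C"),
                 c("G", "A"), c("C", "A"), c("G", "T"), c("C", "T"))
  pairs[sample.int(nrow(pairs), n, replace = TRUE), , drop = FALSE]
}

#' Generate LD-blocked genotype dosages for target and discovery cohorts
#'
#' Haplotypes are built per block by a first-order copying chain: the allele
#' at each variant copies the previous variant's allele with probability
#' `1 - ld_decay`, otherwise it is a fresh Bernoulli(MAF) draw, so
#' adjacent-variant correlation decays geometrically and blocks are mutually
#' independent. The APOE block carries epsilon haplotypes at its first two
#' variant slots: slot 1 is the epsilon2-defining site (alt allele T, as at
#' rs7412), slot 2 the epsilon4-defining site (alt allele C, as at rs429358);
#' the remaining block variants chain off the epsilon4 indicator and so tag
#' the locus.
#'
#' @param config a [sim_config()].
#' @return object of class `dosage_matrix`: list with `dosages` (samples x
#'   variants integer matrix in \{0,1,2\}), `variants` (id, chrom, pos, a1 =
#'   counted/alt allele, a2, maf, block, apoe_slot) and `samples` (iid, role,
#'   pop).
#' @export
gen_ld_genotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  n_unique <- cfg$n_target + cfg$n_discovery -
    (cfg$n_overlap_cases + cfg$n_overlap_controls)
  with_seed(cfg$seed, {
    lay <- block_layout(cfg)
    m <- cfg$snps_per_block
    rho <- 1 - cfg$ld_decay
    nhap <- 2L * n_unique
    pop <- if (cfg$two_pop) rep(1:2, length.out = n_unique) else
      rep(1L, n_unique)
    hap_pop <- rep(pop, each = 2L)
    blocks <- vector("list", cfg$n_blocks)
    vlist <- vector("list", cfg$n_blocks)
    for (b in seq_len(cfg$n_blocks)) {
      maf_b <- stats::runif(1, cfg$maf_range[1], cfg$maf_range[2])
      # Balding-Nichols population frequencies around maf_b
      if (cfg$two_pop) {
        a <- maf_b * (1 - cfg$fst) / cfg$fst
        bb <- (1 - maf_b) * (1 - cfg$fst) / cfg$fst
        maf_pop <- pmin(pmax(stats::rbeta(2, a, bb), 0.01), 0.99)
      } else maf_pop <- maf_b
      pmaf <- if (cfg$two_pop) maf_pop[hap_pop] else rep(maf_b, nhap)
      H <- matrix(0L, nhap, m)
      is_apoe <- b == cfg$apoe_block
      j0 <- 1L
      if (is_apoe) {
        hap_class <- sample(names(cfg$apoe_hap_freqs), nhap, replace = TRUE,
                            prob = cfg$apoe_hap_freqs)
        H[, 1L] <- as.integer(hap_class == "e2")  # eps2 site (alt T)
        H[, 2L] <- as.integer(hap_class == "e4")  # eps4 site (alt C)
        j0 <- 3L
      } else {
        H[, 1L] <- stats::rbinom(nhap, 1L, pmaf)
        j0 <- 2L
      }
      if (j0 <= m) for (j in j0:m) {
        keep <- stats::rbinom(nhap, 1L, rho)
        H[, j] <- ifelse(keep == 1L, H[, j - 1L],
                         stats::rbinom(nhap, 1L, pmaf))
      }
      dos <- H[seq(1L, nhap, 2L), , drop = FALSE] +
        H[seq(2L, nhap, 2L), , drop = FALSE]
      storage.mode(dos) <- "integer"
      blocks[[b]] <- dos
      pos <- lay$start[b] + (seq_len(m) - 1L) * lay$spacing[b]
      al <- allele_pairs(m)
      apoe_slot <- rep(NA_character_, m)
      if (is_apoe) {
        al[1L, ] <- c("T", "C")  # eps2 site: alt T / ref C (rs7412-like)
        al[2L, ] <- c("C", "T")  # eps4 site: alt C / ref T (rs429358-like)
        apoe_slot[1:2] <- c("e2_site", "e4_site")
      }
      vlist[[b]] <- data.frame(
        id = sprintf("snp_%s_%d", lay$chrom[b], pos),
        chrom = lay$chrom[b], pos = pos, a1 = al[, 1], a2 = al[, 2],
        maf = maf_b, block = b, apoe_slot = apoe_slot,
        stringsAsFactors = FALSE)
    }
    dosages <- do.call(cbind, blocks)
    variants <- do.call(rbind, vlist)
    colnames(dosages) <- variants$id
    role <- c(rep("target", cfg$n_target),
              rep("discovery", n_unique - cfg$n_target))
    samples <- data.frame(iid = sprintf("S%05d", seq_len(n_unique)),
                          role = role, pop = pop, stringsAsFactors = FALSE)
    rownames(dosages) <- samples$iid
    structure(list(dosages = dosages, variants = variants, samples = samples),
              class = "dosage_matrix")
  })
}

#' @exportS3Method base::print
print.dosage_matrix <- function(x, ...) {
  cat(sprintf("dosage_matrix: %d samples x %d variants (%d block(s))\n",
              nrow(x$dosages), ncol(x$dosages), length(unique(x$variants$block))))
  invisible(x)
}

#' Plant per-variant liability effects
#'
#' `n_causal` variants outside the APOE block receive conversion-stage
#' effects drawn from a zero-mean normal and rescaled so that the polygenic
#' conversion component has variance `w_convert_poly^2` under
#' Hardy-Weinberg-independent dosages (per-variant variance `2 maf (1-maf)`).
#' The two APOE slots carry the only amyloid-stage effects: `+w_amyloid_apoe`
#' on the epsilon4 site and `-w_amyloid_apoe` on the epsilon2 site (epsilon2
#' protective), and conversion-stage effects `+/- w_convert_apoe` likewise.
#'
#' @param variants the `variants` table of a [gen_ld_genotypes()] result.
#' @param config a [sim_config()].
#' @return data.frame (class `effect_table`): id, beta_amyloid, beta_convert,
#'   causal.
#' @export
plant_effects <- function(variants, config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  non_apoe <- which(variants$block != cfg$apoe_block)
  if (cfg$n_causal > length(non_apoe))
    stop("n_causal exceeds the number of variants outside the APOE block")
  with_seed(cfg$seed + 1L, {
    beta_a <- numeric(nrow(variants))
    beta_c <- numeric(nrow(variants))
    causal <- logical(nrow(variants))
    if (cfg$n_causal > 0L) {
      idx <- sample(non_apoe, cfg$n_causal)
      raw <- stats::rnorm(cfg$n_causal)
      v <- 2 * variants$maf[idx] * (1 - variants$maf[idx])
      s <- cfg$w_convert_poly / sqrt(sum(raw^2 * v))
      beta_c[idx] <- raw * s
      causal[idx] <- TRUE
    }
    i2 <- which(variants$apoe_slot == "e2_site")
    i4 <- which(variants$apoe_slot == "e4_site")
    beta_a[i4] <- cfg$w_amyloid_apoe
    beta_a[i2] <- -cfg$w_amyloid_apoe
    beta_c[i4] <- cfg$w_convert_apoe
    beta_c[i2] <- -cfg$w_convert_apoe
    structure(data.frame(id = variants$id, beta_amyloid = beta_a,
                         beta_convert = beta_c, causal = causal,
                         stringsAsFactors = FALSE),
              class = c("effect_table", "data.frame"))
  })
}

#' Generate two-stage liability phenotypes and visit trajectories
#'
#' Stage 1 (amyloid): liability = amyloid-stage genetic score + N(0,1)
#' noise; subjects above the `amyloid_threshold_quantile` empirical quantile
#' are amyloid-positive. Stage 2 (conversion, defined among the
#' amyloid-positive): liability = conversion-stage genetic score + N(0,1);
#' those above the `convert_threshold_quantile` quantile progress to AD.
#' Converters with the highest conversion liability are already AD at
#' baseline (stable AD); the rest convert MCI->AD at a random visit.
#' Amyloid-positive non-converters are mostly stable MCI; amyloid-negative
#' subjects split between stable control and stable (non-amyloid) MCI.
#' Small label-flip fractions create control->MCI, MCI->control and AD->MCI
#' trajectories. SUVR is `1.11 + 0.3 * (amyloid liability - threshold)`, so
#' the published AV45 cutoff 1.11 reproduces the liability threshold; a
#' `suvr_missing` fraction of subjects has no scan. Age is uniform on
#' \[55, 90\], sex Bernoulli(0.5) coded 0/1.
#'
#' @param dosages a `dosage_matrix`.
#' @param effects an `effect_table` from [plant_effects()].
#' @param config the [sim_config()].
#' @return object of class `cohort_sim`: list with `visits` (IID, SEX, AGE,
#'   VISIT, DX, SUVR; one row per subject-visit) and `truth` (per-subject
#'   simulation truth: role, genetic scores, liabilities, amyloid/conversion
#'   status, disease = amyloid-positive AND converted, trajectory).
#' @export
gen_two_stage_phenotypes <- function(dosages, effects, config) {
  stopifnot(inherits(dosages, "dosage_matrix"),
            inherits(config, "sim_config"))
  cfg <- config
  stopifnot(identical(dosages$variants$id, effects$id))
  G <- dosages$dosages
  n <- nrow(G)
  with_seed(cfg$seed + 2L, {
    g_a <- as.numeric(G %*% effects$beta_amyloid)
    g_c <- as.numeric(G %*% effects$beta_convert)
    liab_a <- g_a + stats::rnorm(n)
    thr_a <- stats::quantile(liab_a, cfg$amyloid_threshold_quantile,
                             names = FALSE)
    pos <- liab_a >= thr_a
    if (!any(pos) || all(pos))
      stop("amyloid threshold produced an empty group")
    liab_c <- g_c + stats::rnorm(n)
    thr_c <- stats::quantile(liab_c[pos], cfg$convert_threshold_quantile,
                             names = FALSE)
    convert <- pos & liab_c >= thr_c
    if (!any(convert) || !any(pos & !convert))
      stop("conversion threshold produced an empty group")
    disease <- convert  # amyloid-positive AND progressed

    traj <- character(n)
    conv_idx <- which(convert)
    # highest conversion liability -> prevalent (stable) AD
    n_prev <- round(cfg$frac_prevalent_ad * length(conv_idx))
    ord <- conv_idx[order(liab_c[conv_idx], decreasing = TRUE)]
    traj[ord[seq_len(n_prev)]] <- "AD_stable"
    traj[setdiff(conv_idx, ord[seq_len(n_prev)])] <- "MCI_to_AD"
    nonconv <- which(pos & !convert)
    u <- stats::runif(length(nonconv))
    traj[nonconv] <- ifelse(u < cfg$frac_pos_nonconv_mci, "MCI_stable",
                            "CN_stable")
    neg <- which(!pos)
    u <- stats::runif(length(neg))
    traj[neg] <- ifelse(u < cfg$frac_neg_mci, "MCI_stable", "CN_stable")
    # post-hoc label flips exercising the excluded / reverted categories
    flip <- function(traj, from, to, rate) {
      i <- which(traj == from)
      if (length(i) && rate > 0) {
        k <- which(stats::runif(length(i)) < rate)
        traj[i[k]] <- to
      }
      traj
    }
    traj <- flip(traj, "CN_stable", "CN_to_MCI", cfg$flip_cn_mci)
    traj <- flip(traj, "MCI_stable", "MCI_to_CN", cfg$flip_mci_cn)
    traj <- flip(traj, "AD_stable", "AD_to_MCI", cfg$flip_ad_mci)

    nv <- cfg$n_visits
    dx_for <- function(tr) {
      switch(tr,
        CN_stable = rep("CN", nv),
        MCI_stable = rep("MCI", nv),
        AD_stable = rep("AD", nv),
        CN_to_MCI = c(rep("CN", nv - 1L), "MCI"),
        MCI_to_CN = c(rep("MCI", nv - 1L), "CN"),
        AD_to_MCI = c(rep("AD", nv - 1L), "MCI"),
        MCI_to_AD = {
          v <- if (nv >= 2L) sample(2:nv, 1L) else 1L
          c(rep("MCI", v - 1L), rep("AD", nv - v + 1L))
        })
    }
    dx <- unlist(lapply(traj, dx_for), use.names = FALSE)

    # floor keeps deep negative liabilities on a physiological SUVR scale
    suvr <- pmax(1.11 + 0.3 * (liab_a - thr_a), 0.6)
    suvr[stats::runif(n) < cfg$suvr_missing] <- NA_real_
    age <- stats::runif(n, 55, 90)
    sex <- stats::rbinom(n, 1L, 0.5)
    iid <- dosages$samples$iid
    visits <- data.frame(
      IID = rep(iid, each = nv), SEX = rep(sex, each = nv),
      AGE = round(rep(age, each = nv), 1), VISIT = rep(seq_len(nv), n),
      DX = dx, SUVR = round(rep(suvr, each = nv), 4),
      stringsAsFactors = FALSE)
    truth <- data.frame(
      iid = iid, role = dosages$samples$role, pop = dosages$samples$pop,
      sex = sex, age = age, g_amyloid = g_a, g_convert = g_c,
      liab_amyloid = liab_a, liab_convert = liab_c,
      amyloid_pos = pos, converter = convert, disease = disease,
      traj = traj, suvr = suvr, stringsAsFactors = FALSE)
    structure(list(visits = visits, truth = truth,
                   thresholds = c(amyloid = thr_a, convert = thr_c)),
              class = "cohort_sim")
  })
}

#' Row indices of the discovery GWAS sample
#'
#' The discovery sample consists of all `role == "discovery"` individuals
#' plus, when the config requests overlap, `n_overlap_cases` target disease
#' cases and `n_overlap_controls` target non-cases (sampled deterministically
#' from the config seed). Their single simulated phenotype is carried into
#' the discovery GWAS, which is what creates genuine discovery-target
#' overlap bias.
#'
#' @param sim a `cohort_sim`.
#' @param config the [sim_config()].
#' @return integer row indices into the dosage/truth tables.
#' @export
discovery_indices <- function(sim, config) {
  stopifnot(inherits(sim, "cohort_sim"), inherits(config, "sim_config"))
  tr <- sim$truth
  idx <- which(tr$role == "discovery")
  k_case <- config$n_overlap_cases
  k_ctrl <- config$n_overlap_controls
  if (k_case + k_ctrl == 0L) return(idx)
  with_seed(config$seed + 3L, {
    tcase <- which(tr$role == "target" & tr$disease)
    tctrl <- which(tr$role == "target" & !tr$disease)
    if (k_case > length(tcase) || k_ctrl > length(tctrl))
      stop("not enough target cases/controls for the requested overlap")
    sort(c(idx, sample(tcase, k_case), sample(tctrl, k_ctrl)))
  })
}

#' Discovery GWAS summary statistics by vectorized logistic score test
#'
#' Per variant, the logistic score test of case status on additive dosage:
#' with null case rate `p0`, score `U = g'(y - p0)` and information
#' `V = p0 (1 - p0) * sum((g - gbar)^2)`; `beta = U/V`, `SE = 1/sqrt(V)`,
#' `p = 2 pnorm(-|beta/SE|)`. Monomorphic variants are excluded (count kept
#' in the `n_monomorphic` attribute).
#'
#' @param dosages dosage matrix (samples x variants) or `dosage_matrix`
#'   restricted upstream to the discovery rows.
#' @param phenotype binary 0/1 vector, one per row.
#' @param variants variant table (required when `dosages` is a bare matrix).
#' @return data.frame of class `sumstat_table` with columns SNP, CHR, BP,
#'   A1 (counted/effect allele), A2, BETA, SE, P, FRQ.
#' @export
gen_discovery_sumstats <- function(dosages, phenotype, variants = NULL) {
  if (inherits(dosages, "dosage_matrix")) {
    variants <- dosages$variants
    G <- dosages$dosages
  } else G <- dosages
  if (is.null(variants)) stop("variant metadata required")
  y <- as.integer(phenotype)
  if (!all(y %in% c(0L, 1L))) stop("discovery phenotype must be binary 0/1")
  if (length(unique(y)) < 2L) stop("constant discovery phenotype")
  if (sum(y == 1L) < 2L || sum(y == 0L) < 2L)
    stop("need at least 2 subjects per class")
  stopifnot(nrow(G) == length(y), ncol(G) == nrow(variants))
  if (anyNA(G)) {
    mu <- colMeans(G, na.rm = TRUE)
    na <- which(is.na(G), arr.ind = TRUE)
    G[na] <- mu[na[, 2]]
  }
  p0 <- mean(y)
  gbar <- colMeans(G)
  U <- as.numeric(crossprod(G, y - p0))
  V <- p0 * (1 - p0) * (colSums(G^2) - nrow(G) * gbar^2)
  mono <- V <= .Machine$double.eps * nrow(G)
  beta <- ifelse(mono, NA_real_, U / V)
  se <- ifelse(mono, NA_real_, 1 / sqrt(V))
  z <- beta / se
  out <- data.frame(SNP = variants$id, CHR = variants$chrom,
                    BP = variants$pos, A1 = variants$a1, A2 = variants$a2,
                    BETA = beta, SE = se,
                    P = 2 * stats::pnorm(-abs(z)),
                    FRQ = gbar / 2, stringsAsFactors = FALSE)
  out <- out[!mono, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_monomorphic") <- sum(mono)
  class(out) <- c("sumstat_table", "data.frame")
  out
}

#' Gene intervals and gene sets over the simulated genome
#'
#' Genes tile each LD block's span (plus a small flank) as disjoint
#' intervals, so every variant falls in exactly one gene. Gene sets are
#' sampled with replacement-free draws per set (sets may overlap one
#' another); the set named by `apoe_set` is guaranteed to contain the gene
#' holding the APOE-like locus, so subtracting the APOE region from pathway
#' scores has real work to do. Default set sizes echo the nine
#' AD-pathway gene counts used in pathway-specific PRS work (the large
#' immune-response set scaled to the simulated gene pool).
#'
#' @param variants variant table of a `dosage_matrix`.
#' @param n_sets number of gene sets.
#' @param set_sizes integer vector (recycled/truncated to `n_sets`).
#' @param seed RNG seed.
#' @param genes_per_block number of genes tiling each block span.
#' @param apoe_set index of the set forced to contain the APOE-like gene.
#' @return list with `genes` (data.frame chrom/start/end/gene, 1-based
#'   closed) and `sets` (named list of gene-id vectors).
#' @export
gen_gene_annotation <- function(variants, n_sets = 9L,
                                set_sizes = c(20L, 10L, 40L, 12L, 11L, 17L,
                                              35L, 18L, 60L),
                                seed = 1L, genes_per_block = 8L,
                                apoe_set = 3L) {
  set_sizes <- rep_len(as.integer(set_sizes), n_sets)
  with_seed(seed + 4L, {
    blocks <- split(variants, variants$block)
    glist <- list()
    gi <- 0L
    for (bl in blocks) {
      lo <- min(bl$pos) - 1000L
      hi <- max(bl$pos) + 1000L
      cuts <- round(seq(lo, hi, length.out = genes_per_block + 1L))
      for (k in seq_len(genes_per_block)) {
        gi <- gi + 1L
        glist[[gi]] <- data.frame(
          chrom = bl$chrom[1], start = cuts[k] + (k > 1L), end = cuts[k + 1L],
          gene = sprintf("GENE%04d", gi), stringsAsFactors = FALSE)
      }
    }
    genes <- do.call(rbind, glist)
    if (any(set_sizes > nrow(genes)))
      stop("set size exceeds number of genes (", nrow(genes), ")")
    # gene containing the eps4 site of the APOE-like locus
    apoe_pos <- variants$pos[match("e4_site", variants$apoe_slot)]
    apoe_chr <- variants$chrom[match("e4_site", variants$apoe_slot)]
    apoe_gene <- genes$gene[genes$chrom == apoe_chr &
                              genes$start <= apoe_pos & genes$end >= apoe_pos][1]
    set_names <- c("protein_lipid_complex_assembly",
                   "regulation_of_beta_amyloid_formation",
                   "protein_lipid_complex",
                   "app_catabolic_process_regulation",
                   "tau_protein_binding",
                   "reverse_cholesterol_transport",
                   "protein_lipid_complex_subunit_organization",
                   "plasma_lipoprotein_particle_assembly",
                   "activation_of_immune_response")
    set_names <- rep_len(set_names, n_sets)
    if (n_sets > 9L)
      set_names <- make.unique(set_names)
    sets <- vector("list", n_sets)
    for (s in seq_len(n_sets)) {
      members <- sample(genes$gene, set_sizes[s])
      if (s == apoe_set && !(apoe_gene %in% members))
        members[1L] <- apoe_gene
      sets[[s]] <- sort(members)
    }
    names(sets) <- set_names
    list(genes = genes, sets = sets)
  })
}
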