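# Discovery-target sample-overlap correction: estimate how much the
# discovery effect sizes would wobble if the overlapping samples were
# removed (a per-variant SD expressed as a multiple c of the discovery SE),
# then average the whole scoring pipeline over summary statistics
# re-sampled with that wobble, re-selecting and re-pruning each time.

# vectorized logistic score-test betas (see gen_discovery_sumstats)
score_betas <- function(G, y) {
  p0 <- mean(y)
  gbar <- colMeans(G)
  U <- as.numeric(crossprod(G, y - p0))
  V <- p0 * (1 - p0) * (colSums(G^2) - nrow(G) * gbar^2)
  V[V <= .Machine$double.eps * nrow(G)] <- NA_real_
  list(beta = U / V, se = 1 / sqrt(V))
}

#' Estimate the overlap SD multiplier c from the discovery cohort
#'
#' For each of `n_sims` replicates, the per-variant discovery effects are
#' refit after randomly excluding `n_exclude_cases` cases and
#' `n_exclude_controls` controls (the counts matching the overlapping
#' samples; 266 and 173 in the reference analysis). The multiplier is
#' `c = mean over variants of SD(beta replicates) / SE_full`; the reference
#' analysis reports c = 0.053, usable as a fixed override downstream.
#'
#' @param dosages discovery `dosage_matrix` or samples-x-variants matrix.
#' @param phenotype binary 0/1 discovery phenotype.
#' @param n_exclude_cases,n_exclude_controls exclusion counts.
#' @param n_sims number of exclusion replicates (reference: 1,000).
#' @param seed RNG seed.
#' @return list: c, mc_se (spread of the per-variant ratios / sqrt(m)),
#'   n_sims, per_variant (the SD/SE ratio per variant).
#' @export
estimate_overlap_sd <- function(dosages, phenotype, n_exclude_cases = 266L,
                                n_exclude_controls = 173L, n_sims = 1000L,
                                seed = 1L) {
  G <- if (inherits(dosages, "dosage_matrix")) dosages$dosages else dosages
  y <- as.integer(phenotype)
  stopifnot(nrow(G) == length(y), all(y %in% c(0L, 1L)))
  cases <- which(y == 1L)
  ctrls <- which(y == 0L)
  if (n_exclude_cases >= length(cases) || n_exclude_controls >= length(ctrls))
    stop("exclusion counts must be smaller than the corresponding arm")
  storage.mode(G) <- "double"
  full <- score_betas(G, y)
  with_seed(seed, {
    B <- matrix(NA_real_, n_sims, ncol(G))
    for (r in seq_len(n_sims)) {
      drop <- c(if (n_exclude_cases > 0L) sample(cases, n_exclude_cases),
                if (n_exclude_controls > 0L) sample(ctrls, n_exclude_controls))
      keep <- if (length(drop)) setdiff(seq_along(y), drop) else seq_along(y)
      B[r, ] <- score_betas(G[keep, , drop = FALSE], y[keep])$beta
    }
    sd_r <- apply(B, 2L, stats::sd)
    ratio <- sd_r / full$se
    ratio <- ratio[is.finite(ratio)]
    list(c = mean(ratio), mc_se = stats::sd(ratio) / sqrt(length(ratio)),
         n_sims = n_sims, per_variant = ratio)
  })
}

#' Perturb summary statistics for one overlap-correction replicate
#'
#' Per variant: `BETA_adj ~ Normal(BETA, c * SE)` and the p-value redefined
#' from the normal approximation, `P_adj = 2 pnorm(-|BETA_adj| / SE)`; SE is
#' unchanged. Works on any table with BETA/SE/P columns (summary-statistic
#' or harmonized weight tables).
#'
#' @param sumstats table with BETA, SE, P.
#' @param c SD multiplier (>= 0); `c = 0` returns the input unchanged.
#' @param seed optional seed (omit to draw from the current RNG stream).
#' @return the table with BETA and P replaced by their adjusted values.
#' @export
perturb_sumstats <- function(sumstats, c, seed = NULL) {
  stopifnot(c >= 0)
  if (c == 0) return(sumstats)
  draw <- function() {
    b <- stats::rnorm(nrow(sumstats), mean = sumstats$BETA,
                      sd = c * sumstats$SE)
    out <- sumstats
    out$BETA <- b
    out$P <- 2 * stats::pnorm(-abs(b / sumstats$SE))
    out
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Average the scoring pipeline over overlap-perturbed summary statistics
#'
#' Each replicate perturbs the harmonized weights with [perturb_sumstats()],
#' re-selects at `p <= p_max` on the adjusted p-values, re-clumps at
#' (`r2_max`, `window_kb`), re-excludes the APOE region, scores the target,
#' adjusts/standardizes against the fixed principal components, and re-fits
#' the three-model battery; the AUCs are summarised across replicates.
#'
#' @param weights harmonized genome-wide `weight_table` (before p-selection).
#' @param dosages target `dosage_matrix`.
#' @param contrast data.frame (IID, case).
#' @param scores score-set data.frame (IID, EPS2, EPS4, SEX, AGE); its
#'   PRS_STD column is replaced per replicate.
#' @param c overlap SD multiplier (e.g. the estimate or the reference
#'   0.053).
#' @param n_sims replicates (reference analysis: 10,000; default 200 - the
#'   summary reports the count used).
#' @param seed RNG seed.
#' @param pcs principal-component matrix for adjustment (NULL = plain
#'   standardization).
#' @param p_max,r2_max,window_kb,apoe_region pipeline settings.
#' @return list: `summary` (per model/auc-type mean, sd, quantiles),
#'   `replicates` (per-replicate AUC table), n_sims, c, seed.
#' @export
simulate_corrected_auc <- function(weights, dosages, contrast, scores, c,
                                   n_sims = 200L, seed = 1L, pcs = NULL,
                                   p_max = 0.5, r2_max = 0.1,
                                   window_kb = 1000,
                                   apoe_region = apoe_region_default()) {
  stopifnot(inherits(dosages, "dosage_matrix"))
  with_seed(seed, {
    reps <- vector("list", n_sims)
    for (r in seq_len(n_sims)) {
      w <- perturb_sumstats(weights, c)
      w <- select_by_p(w, p_max)
      w <- ld_clump(w, dosages, r2_max = r2_max, window_kb = window_kb)
      w <- exclude_region(w, apoe_region)
      raw <- compute_raw_prs(dosages, w)
      std <- adjust_standardize(raw, pcs)
      sc <- scores
      sc$PRS_STD <- std[match(sc$IID, dosages$samples$iid)]
      bat <- run_model_battery(contrast, sc)
      reps[[r]] <- data.frame(rep = r, bat$aucs,
                              lrt_p = bat$lrt_full_vs_apoe$p,
                              n_snps = nrow(w))
    }
    rep_tab <- do.call(rbind, reps)
    agg <- function(v) c(mean = mean(v), sd = stats::sd(v),
                         stats::quantile(v, c(0.025, 0.5, 0.975)))
    keys <- unique(rep_tab$model)
    summ <- do.call(rbind, lapply(keys, function(k) {
      sub <- rep_tab[rep_tab$model == k, ]
      data.frame(model = k,
                 auc_type = c("auc_bare", "auc_cov"),
                 rbind(agg(sub$auc_bare), agg(sub$auc_cov)),
                 check.names = FALSE, stringsAsFactors = FALSE)
    }))
    rownames(summ) <- NULL
    list(summary = summ, replicates = rep_tab, n_sims = n_sims, c = c,
         seed = seed)
  })
}
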