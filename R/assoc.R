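# Nested logistic models per contrast: APOE-only, PRS-only and full
# (APOE + PRS) predictors, paired AUCs with and without age/sex, the
# likelihood-ratio (anova) comparison of full vs APOE, the +/-1.5 SD
# extremes re-run, and Bonferroni flagging for the pathway battery.

#' Fit a logistic model and return a tidy fit object
#'
#' Maximum-likelihood logistic regression of a binary outcome on the given
#' predictors (plus optional covariates, by convention sex and age).
#' Perfect separation raises an explicit error naming the offending
#' predictor.
#'
#' @param outcome binary 0/1 vector.
#' @param predictors data.frame/matrix of predictors (may be NULL for an
#'   intercept-only fit).
#' @param covariates optional data.frame/matrix appended to the design.
#' @return object of class `prs_fit`: coefficient table (term, beta, se, z,
#'   p), log-likelihood, deviance, fitted probabilities, predictor manifest,
#'   n, and the underlying `glm` fit.
#' @export
fit_logistic <- function(outcome, predictors = NULL, covariates = NULL) {
  y <- as.integer(outcome)
  stopifnot(all(y %in% c(0L, 1L)))
  X <- NULL
  if (!is.null(predictors)) X <- as.data.frame(predictors)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    X <- if (is.null(X)) covariates else cbind(X, covariates)
  }
  dat <- if (is.null(X)) data.frame(y = y) else data.frame(y = y, X)
  fit <- suppressWarnings(
    stats::glm(y ~ ., family = stats::binomial(), data = dat))
  co <- summary(fit)$coefficients
  # perfect separation drives the deviance to zero; sparse-cell
  # quasi-separation keeps a positive deviance and is left to the caller
  sep <- length(stats::coef(fit)) > 1L && fit$deviance < 1e-6
  if (sep) {
    worst <- names(which.max(abs(stats::coef(fit)[-1])))
    stop("perfect separation detected for predictor '", worst, "'")
  }
  manifest <- sort(setdiff(names(dat), "y"))
  structure(list(
    coefficients = data.frame(term = rownames(co), beta = co[, 1],
                              se = co[, 2], z = co[, 3], p = co[, 4],
                              row.names = NULL, stringsAsFactors = FALSE),
    loglik = as.numeric(stats::logLik(fit)),
    deviance = fit$deviance,
    fitted = fit$fitted.values,
    manifest = manifest, n = length(y), outcome = y, glm = fit),
    class = "prs_fit")
}

#' @exportS3Method base::print
print.prs_fit <- function(x, ...) {
  cat(sprintf("logistic fit: n = %d, predictors = {%s}, deviance = %.2f\n",
              x$n, paste(x$manifest, collapse = ", "), x$deviance))
  print(x$coefficients, digits = 3)
  invisible(x)
}

#' Paired AUCs for a predictor set, without and with age/sex
#'
#' Fits the model twice - predictors only, and predictors plus covariates -
#' and reports the rank-based AUC of each model's fitted probabilities.
#'
#' @param outcome binary 0/1 vector.
#' @param predictors data.frame of predictors.
#' @param covariates data.frame of covariates (sex, age).
#' @return named vector `c(auc_bare, auc_cov)` with the two fits attached as
#'   attributes `fit_bare` / `fit_cov`.
#' @export
auc_pair <- function(outcome, predictors, covariates) {
  f1 <- fit_logistic(outcome, predictors, covariates = NULL)
  f2 <- fit_logistic(outcome, predictors, covariates = covariates)
  out <- c(auc_bare = auc_rank(f1$fitted, outcome),
           auc_cov = auc_rank(f2$fitted, outcome))
  attr(out, "fit_bare") <- f1
  attr(out, "fit_cov") <- f2
  out
}

#' Likelihood-ratio (anova) test of nested logistic fits
#'
#' Chi-square test on the deviance difference, the standard nested-model
#' comparison for binomial fits.
#'
#' @param full,reduced `prs_fit` objects on the same samples, with the
#'   reduced predictor manifest a subset of the full one.
#' @return list: delta_deviance, delta_df, p, plus both fits.
#' @export
lrt_nested <- function(full, reduced) {
  stopifnot(inherits(full, "prs_fit"), inherits(reduced, "prs_fit"))
  if (!all(reduced$manifest %in% full$manifest))
    stop("models are not nested (reduced manifest not a subset)")
  if (full$n != reduced$n || !identical(full$outcome, reduced$outcome))
    stop("models were fitted on different samples")
  dd <- reduced$deviance - full$deviance
  ddf <- length(full$manifest) - length(reduced$manifest)
  p <- if (ddf == 0L) 1 else stats::pchisq(dd, df = ddf, lower.tail = FALSE)
  list(delta_deviance = dd, delta_df = ddf, p = p,
       full = full, reduced = reduced)
}

#' Subjects in the extremes of a standardized score
#'
#' @param scores named standardized score vector.
#' @param k SD multiplier; subjects with `|score| > k` are retained.
#' @return names (or indices when unnamed) of retained subjects.
#' @export
extreme_subset <- function(scores, k = 1.5) {
  sel <- abs(scores) > k
  if (is.null(names(scores))) which(sel) else names(scores)[sel]
}

#' Bonferroni-corrected significance threshold
#'
#' `alpha / m`; with the default 27 tests (3 scenarios x 9 pathways) this is
#' 1.85e-3.
#'
#' @param alpha family-wise level.
#' @param m number of tests.
#' @export
bonferroni_alpha <- function(alpha = 0.05, m = 27L) {
  stopifnot(m >= 1L)
  alpha / m
}

#' Genome-wide model battery for one contrast
#'
#' Fits the three predictor models - (1) APOE (eps2 + eps4), (2) PRS
#' without APOE, (3) full (both) - each with sex and age as covariates,
#' reports paired AUCs (without / with covariates), and the
#' likelihood-ratio p-value of the full model over APOE alone. Optionally
#' re-runs the full-model AUC in the +/-`extremes_k` SD score extremes.
#'
#' @param contrast data.frame (IID, case).
#' @param scores score-set data.frame with columns IID, PRS_STD, EPS2, EPS4,
#'   SEX, AGE.
#' @param extremes_k optional SD cutoff for the extremes re-run.
#' @return object of class `model_battery`.
#' @export
run_model_battery <- function(contrast, scores, extremes_k = NULL) {
  need_cols(scores, c("IID", "PRS_STD", "EPS2", "EPS4", "SEX", "AGE"),
            "score set")
  d <- merge(contrast, scores, by = "IID")
  d <- d[stats::complete.cases(d[, c("case", "PRS_STD", "EPS2", "EPS4",
                                     "SEX", "AGE")]), ]
  if (!sum(d$case) || !sum(!d$case)) stop("contrast has an empty arm")
  covs <- d[, c("SEX", "AGE")]
  preds <- list(apoe = d[, c("EPS2", "EPS4")],
                prs = d[, "PRS_STD", drop = FALSE],
                full = d[, c("EPS2", "EPS4", "PRS_STD")])
  models <- lapply(preds, function(p) auc_pair(d$case, p, covs))
  lrt <- lrt_nested(attr(models$full, "fit_cov"),
                    attr(models$apoe, "fit_cov"))
  aucs <- do.call(rbind, lapply(models, function(m)
    data.frame(auc_bare = m[["auc_bare"]], auc_cov = m[["auc_cov"]])))
  aucs$model <- names(models)
  extremes <- NULL
  if (!is.null(extremes_k)) {
    s <- d$PRS_STD
    names(s) <- d$IID
    ids <- extreme_subset(s, extremes_k)
    e <- d[d$IID %in% ids, , drop = FALSE]
    if (sum(e$case) && sum(!e$case)) {
      # small tails can separate on a covariate; report only when estimable
      me <- tryCatch(auc_pair(e$case, e[, c("EPS2", "EPS4", "PRS_STD")],
                              e[, c("SEX", "AGE")]),
                     error = function(cnd) NULL)
      if (!is.null(me))
        extremes <- list(k = extremes_k, n = nrow(e),
                         auc_bare = me[["auc_bare"]],
                         auc_cov = me[["auc_cov"]])
    }
  }
  structure(list(
    n = c(case = sum(d$case), control = sum(!d$case)),
    models = models,
    aucs = aucs[, c("model", "auc_bare", "auc_cov")],
    lrt_full_vs_apoe = lrt[c("delta_deviance", "delta_df", "p")],
    extremes = extremes), class = "model_battery")
}

#' @exportS3Method base::print
print.model_battery <- function(x, ...) {
  cat(sprintf("model battery: %d cases / %d controls\n",
              x$n["case"], x$n["control"]))
  print(x$aucs, digits = 3, row.names = FALSE)
  cat(sprintf("LRT full vs APOE: chi2 = %.2f (df %d), p = %.3g\n",
              x$lrt_full_vs_apoe$delta_deviance, x$lrt_full_vs_apoe$delta_df,
              x$lrt_full_vs_apoe$p))
  if (!is.null(x$extremes))
    cat(sprintf("extremes |PRS| > %.1f SD: n = %d, AUC = %.3f/%.3f\n",
                x$extremes$k, x$extremes$n, x$extremes$auc_bare,
                x$extremes$auc_cov))
  invisible(x)
}

#' Pathway-score battery for one contrast
#'
#' For every pathway-score column (and the whole-genome-minus-pathways
#' complement), fits `case ~ score + sex + age` and reports the score's
#' beta, SE and p-value, flagged against the Bonferroni threshold
#' `alpha / m`.
#'
#' @param contrast data.frame (IID, case).
#' @param scores score-set data.frame (IID, SEX, AGE plus the score
#'   columns).
#' @param score_cols character vector of score column names to test.
#' @param alpha,m Bonferroni parameters (defaults 0.05 and 27).
#' @return data.frame: score, beta, se, p, significant.
#' @export
battery_pathways <- function(contrast, scores, score_cols,
                             alpha = 0.05, m = 27L) {
  need_cols(scores, c("IID", "SEX", "AGE", score_cols), "score set")
  d <- merge(contrast, scores, by = "IID")
  thr <- bonferroni_alpha(alpha, m)
  rows <- lapply(score_cols, function(sc) {
    dd <- d[stats::complete.cases(d[, c("case", sc, "SEX", "AGE")]), ]
    fit <- fit_logistic(dd$case, dd[, sc, drop = FALSE],
                        dd[, c("SEX", "AGE")])
    co <- fit$coefficients[fit$coefficients$term == sc, ]
    data.frame(score = sc, beta = co$beta, se = co$se, p = co$p,
               significant = co$p <= thr, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "bonferroni") <- thr
  out
}
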