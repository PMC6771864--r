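# Independent oracles and small fixture builders shared across tests.

# small, fast simulation config for unit tests; overrides win, and the
# causal count is capped to the available non-APOE variants
small_config <- function(seed = 1L, ...) {
  args <- list(seed = seed, n_target = 250L, n_discovery = 400L,
               n_blocks = 8L, snps_per_block = 12L, n_causal = 30L)
  dots <- list(...)
  args[names(dots)] <- dots
  if (!"n_causal" %in% names(dots))
    args$n_causal <- min(args$n_causal,
                         (args$n_blocks - 1L) * args$snps_per_block)
  do.call(sim_config, args)
}

# correlated dosage matrix via the same first-order idea but standalone code
gen_corr_dosages <- function(n, m, rho, maf = 0.3, seed = 1L) {
  set.seed(seed)
  hap <- function() {
    h <- matrix(0L, n, m)
    h[, 1] <- rbinom(n, 1, maf)
    if (m > 1) for (j in 2:m) {
      keep <- rbinom(n, 1, rho) == 1
      h[, j] <- ifelse(keep, h[, j - 1], rbinom(n, 1, maf))
    }
    h
  }
  hap() + hap()
}

# exhaustive greedy clumping oracle: precomputed r2 matrix, explicit loop
oracle_clump <- function(w, G, r2_max, window_kb) {
  R2 <- suppressWarnings(stats::cor(G[, w$SNP, drop = FALSE]))^2
  remaining <- seq_len(nrow(w))
  kept <- integer(0)
  while (length(remaining)) {
    o <- remaining[order(w$P[remaining], w$CHR[remaining], w$BP[remaining])]
    idx <- o[1]
    kept <- c(kept, idx)
    remaining <- setdiff(remaining, idx)
    prune <- remaining[w$CHR[remaining] == w$CHR[idx] &
                         abs(w$BP[remaining] - w$BP[idx]) <= window_kb * 1000]
    if (length(prune)) {
      r2 <- R2[idx, prune]
      remaining <- setdiff(remaining, prune[!is.na(r2) & r2 >= r2_max])
    }
  }
  sort(w$SNP[kept])
}

# random weight table + dosages for clumping property tests
random_clump_instance <- function(n_var, n_samp = 60, seed = 1L) {
  set.seed(seed)
  chr <- sample(c("1", "2"), n_var, replace = TRUE)
  bp <- sample.int(5e6, n_var)
  G <- gen_corr_dosages(n_samp, n_var, rho = runif(1, 0.3, 0.95),
                        seed = seed + 1L)
  ids <- sprintf("v%04d", seq_len(n_var))
  colnames(G) <- ids
  w <- data.frame(SNP = ids, CHR = chr, BP = bp, A1 = "A", A2 = "G",
                  BETA = rnorm(n_var), SE = runif(n_var, 0.05, 0.2),
                  P = signif(runif(n_var), 3), stringsAsFactors = FALSE)
  class(w) <- c("weight_table", "data.frame")
  list(w = w, G = G)
}

# hand-rolled IRLS for logistic regression
oracle_irls <- function(X, y, tol = 1e-12, maxit = 50) {
  X <- cbind(1, as.matrix(X))
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    z <- eta + (y - mu) / W
    beta_new <- solve(crossprod(X, W * X), crossprod(X, W * z))
    if (max(abs(beta_new - beta)) < tol) return(drop(beta_new))
    beta <- drop(beta_new)
  }
  beta
}

# normal-equations least squares residuals
oracle_ols_resid <- function(y, X) {
  X <- cbind(1, as.matrix(X))
  y - drop(X %*% solve(crossprod(X), crossprod(X, y)))
}

# exact HWE p-value by direct enumeration with choose() products
oracle_hwe <- function(naa, nab, nbb) {
  n <- naa + nab + nbb
  nb <- 2 * nbb + nab
  hets <- seq(nb %% 2, min(nb, 2 * n - nb), by = 2)
  pr <- vapply(hets, function(h) {
    nb_hom <- (nb - h) / 2
    na_hom <- n - nb_hom - h
    exp(lchoose(n, na_hom) + lchoose(n - na_hom, h) + h * log(2))
  }, numeric(1))
  # normalize (constant factors cancel)
  pr <- pr / sum(pr)
  obs <- pr[hets == nab]
  sum(pr[pr <= obs + 1e-12])
}

# tiny visit-table builder: list of DX vectors -> data.frame
visits_from <- function(dx_list, suvr = NULL) {
  ids <- sprintf("P%03d", seq_along(dx_list))
  do.call(rbind, lapply(seq_along(dx_list), function(i) {
    nv <- length(dx_list[[i]])
    data.frame(IID = ids[i], SEX = 0L, AGE = 70, VISIT = seq_len(nv),
               DX = dx_list[[i]],
               SUVR = if (is.null(suvr)) NA_real_ else suvr[i],
               stringsAsFactors = FALSE)
  }))
}
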