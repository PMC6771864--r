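test_that("exact HWE test matches an enumeration oracle and flags imbalance", {
  cases <- list(c(50, 0, 50), c(20, 50, 30), c(100, 10, 1), c(5, 5, 5),
                c(0, 10, 0), c(988, 10, 2))
  for (k in cases) {
    expect_equal(hwe_exact_p(k[1], k[2], k[3]),
                 oracle_hwe(k[1], k[2], k[3]), tolerance = 1e-9,
                 info = paste(k, collapse = ","))
  }
  expect_lt(hwe_exact_p(50, 0, 50), 1e-6)
})

test_that("variant QC removes high-missingness, HWE-failing and rare variants", {
  set.seed(1)
  n <- 400
  G <- cbind(good = rbinom(n, 2, 0.3),
             missy = rbinom(n, 2, 0.3),
             hwe_bad = sample(rep(c(0L, 2L), each = n / 2)),
             rare = rbinom(n, 2, 0.004),
             mono = rep(0L, n))
  G[1:12, "missy"] <- NA  # 3% missing
  v <- data.frame(id = colnames(G), chrom = "1",
                  pos = seq(1e6, by = 1e5, length.out = 5),
                  a1 = "A", a2 = "G", stringsAsFactors = FALSE)
  keep <- variant_qc(G, v)
  expect_identical(as.character(keep), "good")
  ct <- attr(keep, "counts")
  expect_equal(unname(ct["fail_missingness"]), 1)
  expect_gte(unname(ct["fail_hwe"]), 1)
  expect_gte(unname(ct["fail_maf"]), 2)
})

test_that("allele harmonization resolves swaps and strand flips, drops palindromes", {
  tv <- data.frame(id = paste0("v", 1:5), chrom = "1",
                   pos = c(100, 200, 300, 400, 500) * 1000L,
                   a1 = c("A", "G", "A", "A", "C"),
                   a2 = c("G", "A", "C", "T", "G"),  # v4 A/T, v5 C/G palindromic
                   stringsAsFactors = FALSE)
  ss <- data.frame(SNP = paste0("s", 1:5), CHR = "1",
                   BP = c(100, 200, 300, 400, 500) * 1000L,
                   A1 = c("A", "A", "T", "A", "C"),
                   A2 = c("G", "G", "G", "T", "G"),
                   BETA = c(0.1, 0.1, 0.2, 0.3, 0.4),
                   SE = 0.05, P = 0.01, FRQ = 0.3, stringsAsFactors = FALSE)
  w <- match_alleles(tv, ss)
  expect_identical(w$SNP, c("v1", "v2", "v3"))
  expect_equal(w$BETA, c(0.1, -0.1, 0.2))  # exact, swap, strand-flip
  ct <- attr(w, "counts")
  expect_equal(unname(ct["n_palindromic_dropped"]), 2)
})

test_that("a ten-variant table with two palindromes yields eight weights", {
  set.seed(2)
  tv <- data.frame(id = paste0("v", 1:10), chrom = "1",
                   pos = (1:10) * 1e5,
                   a1 = c(rep("A", 8), "A", "C"),
                   a2 = c(rep("G", 8), "T", "G"), stringsAsFactors = FALSE)
  ss <- data.frame(SNP = tv$id, CHR = tv$chrom, BP = tv$pos, A1 = tv$a1,
                   A2 = tv$a2, BETA = rnorm(10), SE = 0.05, P = 0.5,
                   FRQ = 0.2, stringsAsFactors = FALSE)
  expect_equal(nrow(match_alleles(tv, ss)), 8L)
})

test_that("p-value selection is boundary inclusive", {
  w <- data.frame(SNP = c("a", "b", "c"), CHR = "1", BP = 1:3, A1 = "A",
                  A2 = "G", BETA = 1, SE = 1, P = c(0.5, 0.500001, 0.01))
  expect_identical(select_by_p(w, 0.5)$SNP, c("a", "c"))
  expect_equal(nrow(select_by_p(w, 1)), 3L)
  set.seed(3)
  wn <- data.frame(SNP = as.character(1:10000), CHR = "1", BP = 1:10000,
                   A1 = "A", A2 = "G", BETA = 0, SE = 1, P = runif(10000))
  n_kept <- nrow(select_by_p(wn, 0.5))
  expect_lt(abs(n_kept - 5000), 4 * sqrt(10000 * 0.25))
})

test_that("clumping keeps the most-associated variant per window", {
  G <- gen_corr_dosages(200, 2, rho = 0.8, seed = 4)
  colnames(G) <- c("lead", "shadow")
  w <- data.frame(SNP = c("lead", "shadow"), CHR = "1",
                  BP = c(1e6, 1.5e6),  # 500 kb apart
                  A1 = "A", A2 = "G", BETA = 1, SE = 1, P = c(1e-8, 1e-4))
  out <- ld_clump(w, G, r2_max = 0.1, window_kb = 1000)
  expect_identical(out$SNP, "lead")
  # outside the window both survive regardless of correlation
  w$BP <- c(1e6, 2.5e6)  # 1500 kb
  expect_equal(nrow(ld_clump(w, G, r2_max = 0.1, window_kb = 1000)), 2L)
  expect_error(ld_clump(w, G, window_kb = 0), "window_kb")
  expect_error(ld_clump(w, G, r2_max = 0), "r2_max")
})

test_that("clumping equals the brute-force greedy oracle on random instances", {
  for (s in 1:40) {
    inst <- random_clump_instance(sample(10:200, 1), seed = s)
    got <- ld_clump(inst$w, inst$G, r2_max = 0.1, window_kb = 1000)
    expect_identical(sort(got$SNP),
                     oracle_clump(inst$w, inst$G, 0.1, 1000),
                     info = paste("seed", s))
  }
})

test_that("region exclusion respects chromosome and closed boundaries", {
  w <- data.frame(SNP = paste0("v", 1:4), CHR = c("19", "19", "19", "1"),
                  BP = c(45000000, 44399999, 46500000, 45000000),
                  A1 = "A", A2 = "G", BETA = 1, SE = 1, P = 0.1)
  out <- exclude_region(w, apoe_region_default())
  expect_identical(out$SNP, c("v2", "v4"))
  expect_equal(attr(out, "n_excluded"), 2L)
})

test_that("epsilon-allele counts follow the diplotype table", {
  cfg <- small_config(seed = 23)
  dm <- gen_ld_genotypes(cfg)
  ap <- apoe_allele_counts(dm)
  e2 <- dm$dosages[, dm$variants$id[match("e2_site", dm$variants$apoe_slot)]]
  e4 <- dm$dosages[, dm$variants$id[match("e4_site", dm$variants$apoe_slot)]]
  expect_identical(ap$eps2, unname(e2))
  expect_identical(ap$eps4, unname(e4))
  expect_true(all(ap$eps2 + ap$eps4 <= 2, na.rm = TRUE))
  # frequency consistency with the generating haplotype frequencies
  expect_lt(abs(mean(ap$eps4) / 2 - 0.15), 0.04)
  expect_lt(abs(mean(ap$eps2) / 2 - 0.08), 0.04)
})

test_that("APOE weight estimation recovers planted effects and the null", {
  set.seed(31)
  n <- 5000
  hap <- function() sample(c("e2", "e3", "e4"), n, TRUE,
                           prob = c(0.08, 0.77, 0.15))
  h1 <- hap(); h2 <- hap()
  eps2 <- (h1 == "e2") + (h2 == "e2")
  eps4 <- (h1 == "e4") + (h2 == "e4")
  eta <- -1 - 0.8 * eps2 + 1.2 * eps4
  y <- rbinom(n, 1, plogis(eta))
  ct <- data.frame(IID = as.character(1:n), case = y)
  ap <- data.frame(IID = as.character(1:n), eps2 = eps2, eps4 = eps4)
  est <- estimate_apoe_weights(ct, ap)
  expect_lt(abs(est$beta_eps2 - (-0.8)), 3 * est$se[1])
  expect_lt(abs(est$beta_eps4 - 1.2), 3 * est$se[2])
  # null phenotype: both within 3 SE of zero
  ct$case <- rbinom(n, 1, 0.3)
  est0 <- estimate_apoe_weights(ct, ap)
  expect_lt(abs(est0$beta_eps2), 3 * est0$se[1])
  expect_lt(abs(est0$beta_eps4), 3 * est0$se[2])
  # override passes through untouched
  ov <- estimate_apoe_weights(ct, ap, override = c(-1.04, 1.55))
  expect_equal(c(ov$beta_eps2, ov$beta_eps4), c(-1.04, 1.55))
})

test_that("raw PRS equals the dot-product oracle and handles trivial cases", {
  w1 <- data.frame(SNP = "v1", CHR = "1", BP = 1e6, A1 = "A", A2 = "G",
                   BETA = 1.55, SE = 0.1, P = 0.01)
  G <- matrix(c(0L, 2L), 2, 1, dimnames = list(c("a", "b"), "v1"))
  expect_equal(unname(compute_raw_prs(G, w1)), c(0, 3.10))
  set.seed(41)
  G <- matrix(rbinom(100 * 50, 2, 0.3), 100, 50,
              dimnames = list(NULL, paste0("v", 1:50)))
  w <- data.frame(SNP = paste0("v", 1:50), CHR = "1", BP = (1:50) * 1e4,
                  A1 = "A", A2 = "G", BETA = rnorm(50), SE = 0.1, P = 0.5)
  oracle <- vapply(seq_len(100), function(i) sum(G[i, ] * w$BETA), numeric(1))
  expect_equal(unname(compute_raw_prs(G, w)), oracle, tolerance = 1e-10)
  w$SNP <- paste0("x", 1:50)
  expect_error(compute_raw_prs(G, w), "no overlapping")
})

test_that("scores are invariant to variant and sample ordering", {
  cfg <- small_config(seed = 43)
  dm <- gen_ld_genotypes(cfg)
  set.seed(43)
  w <- data.frame(SNP = dm$variants$id, CHR = dm$variants$chrom,
                  BP = dm$variants$pos, A1 = dm$variants$a1,
                  A2 = dm$variants$a2, BETA = rnorm(nrow(dm$variants)),
                  SE = 0.1, P = 0.5)
  s1 <- compute_raw_prs(dm, w)
  s2 <- compute_raw_prs(dm, w[sample(nrow(w)), ])
  expect_equal(s1, s2)
  perm <- sample(nrow(dm$dosages))
  s3 <- compute_raw_prs(subset_dosages(dm, rows = perm), w)
  expect_equal(unname(s3), unname(s1[perm]))
})

test_that("principal components are orthonormal and permutation-equivariant", {
  cfg <- small_config(seed = 47)
  dm <- gen_ld_genotypes(cfg)
  pcs <- compute_pcs(dm, k = 8)
  expect_equal(crossprod(pcs), diag(8), tolerance = 1e-8,
               ignore_attr = TRUE)
  set.seed(47)
  perm <- sample(nrow(dm$dosages))
  pcs_p <- compute_pcs(subset_dosages(dm, rows = perm), k = 8)
  # same subspace row-permuted (columns may flip sign)
  agree <- unname(abs(diag(crossprod(pcs_p, pcs[perm, ]))))
  expect_equal(agree, rep(1, 8), tolerance = 1e-6)
  expect_error(compute_pcs(dm$dosages[1:5, 1:3], k = 8), "rank")
})

test_that("PC1 separates two simulated populations", {
  cfg <- sim_config(seed = 53, n_target = 600, n_discovery = 100,
                    n_blocks = 10, snps_per_block = 20, two_pop = TRUE,
                    fst = 0.1, n_causal = 0, ld_decay = 1)
  dm <- gen_ld_genotypes(cfg)
  pcs <- compute_pcs(dm, k = 2)
  pop <- dm$samples$pop
  auc <- auc_rank(pcs[, 1], as.integer(pop == 2))
  expect_gt(max(auc, 1 - auc), 0.95)
})

test_that("covariate adjustment leaves orthogonal standardized residuals", {
  set.seed(59)
  n <- 300
  X <- cbind(pc1 = rnorm(n), pc2 = rnorm(n), age = runif(n, 55, 90))
  y <- 2 + X %*% c(0.5, -1, 0.02) + rnorm(n)
  z <- adjust_standardize(drop(y), X)
  expect_equal(mean(z), 0, tolerance = 1e-8)
  expect_equal(sd(z), 1, tolerance = 1e-8)
  for (j in 1:3) expect_lt(abs(cor(z, X[, j])), 1e-8)
  # matches the normal-equations oracle after scaling
  r <- oracle_ols_resid(drop(y), X)
  expect_equal(z, (r - mean(r)) / sd(r), tolerance = 1e-10)
  expect_error(adjust_standardize(drop(y), cbind(X, X[, 1])), "rank")
})

test_that("pathway partition respects set semantics and the APOE subtraction", {
  w <- data.frame(SNP = paste0("v", 1:6), CHR = c("1", "1", "1", "1", "19", "2"),
                  BP = c(150e3, 250e3, 350e3, 950e3, 45e6, 100e3),
                  A1 = "A", A2 = "G", BETA = 1, SE = 1, P = 0.1)
  genes <- data.frame(chrom = c("1", "1", "1", "19"),
                      start = c(100000L, 300000L, 120000L, 44900000L),
                      end = c(200000L, 400000L, 160000L, 45100000L),
                      gene = c("GA", "GB", "GC", "GAPOE"))
  sets <- list(s1 = c("GA", "GB"), s2 = c("GC", "GAPOE"), s3 = "GMISSING")
  part <- pathway_partition(w, sets, genes)
  expect_identical(part$pathways$s1$SNP, c("v1", "v3"))
  # v1 sits in overlapping genes GA and GC, hence in both s1 and s2
  expect_true("v1" %in% part$pathways$s2$SNP)
  expect_true("v5" %in% part$pathways$s2$SNP)
  expect_identical(attr(part, "unmapped"), "GMISSING")
  # complement = weights in no pathway
  expect_identical(part$complement$SNP, c("v2", "v4", "v6"))
  # union + complement recovers the full table as sets
  all_ids <- sort(unique(c(unlist(lapply(part$pathways, `[[`, "SNP")),
                           part$complement$SNP)))
  expect_identical(all_ids, sort(w$SNP))
  # APOE subtraction empties the APOE-region variants from pathways
  part_no <- pathway_partition(w, sets, genes, drop_apoe = TRUE)
  expect_false("v5" %in% part_no$pathways$s2$SNP)
})

test_that("union-plus-complement identity holds on random fixtures", {
  for (s in 1:10) {
    set.seed(s)
    n <- 40
    w <- data.frame(SNP = paste0("v", 1:n), CHR = "1",
                    BP = sort(sample.int(2e6, n)), A1 = "A", A2 = "G",
                    BETA = 1, SE = 1, P = 0.1)
    genes <- data.frame(chrom = "1", start = seq(1L, 2e6, by = 2e5),
                        end = seq(1L, 2e6, by = 2e5) + 150000L,
                        gene = paste0("G", 1:10))
    sets <- list(a = sample(genes$gene, 4), b = sample(genes$gene, 5))
    part <- pathway_partition(w, sets, genes)
    in_path <- unique(unlist(lapply(part$pathways, `[[`, "SNP")))
    expect_identical(sort(c(in_path, part$complement$SNP)), sort(w$SNP))
    expect_length(intersect(in_path, part$complement$SNP), 0)
  }
})
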