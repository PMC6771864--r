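test_that("genotype generation is a pure function of the config seed", {
  cfg <- small_config(seed = 7)
  a <- gen_ld_genotypes(cfg)
  b <- gen_ld_genotypes(cfg)
  expect_identical(a$dosages, b$dosages)
  expect_identical(a$variants, b$variants)
  d <- gen_ld_genotypes(small_config(seed = 8))
  expect_false(identical(a$dosages, d$dosages))
  expect_true(all(a$dosages %in% 0:2))
  # positions strictly increasing within chromosome, blocks > 1000 kb apart
  for (ch in unique(a$variants$chrom)) {
    v <- a$variants[a$variants$chrom == ch, ]
    expect_true(all(diff(v$pos) > 0))
    starts <- tapply(v$pos, v$block, min)
    ends <- tapply(v$pos, v$block, max)
    if (length(starts) > 1)
      expect_true(all(sort(starts)[-1] - sort(ends)[-length(ends)] > 1e6))
  }
})

test_that("ld_decay = 1 gives independent variants and MAF is recovered", {
  cfg <- sim_config(seed = 3, n_target = 49000, n_discovery = 1000,
                    n_blocks = 2, snps_per_block = 5, ld_decay = 1,
                    maf_range = c(0.3, 0.3), n_causal = 0)
  dm <- gen_ld_genotypes(cfg)
  G <- dm$dosages
  non_apoe <- dm$variants$id[dm$variants$block != cfg$apoe_block]
  r2 <- cor(G[, non_apoe])^2
  expect_lt(max(r2[upper.tri(r2)]), 0.005)
  frq <- colMeans(G[, non_apoe]) / 2
  expect_true(all(abs(frq - 0.3) < 0.01))
})

test_that("adjacent-variant LD decays with the copying parameter", {
  cfg <- sim_config(seed = 5, n_target = 5000, n_discovery = 100,
                    n_blocks = 3, snps_per_block = 10, ld_decay = 0.1,
                    n_causal = 0)
  dm <- gen_ld_genotypes(cfg)
  v <- dm$variants[dm$variants$block == 1, ]
  r_adj <- mean(vapply(seq_len(nrow(v) - 1), function(j)
    cor(dm$dosages[, v$id[j]], dm$dosages[, v$id[j + 1]]), numeric(1)))
  # expected adjacent haplotype correlation = 1 - ld_decay = 0.9
  expect_gt(r_adj, 0.8)
  far <- cor(dm$dosages[, v$id[1]], dm$dosages[, v$id[nrow(v)]])
  expect_lt(abs(far), r_adj)
})

test_that("planted effects respect sign convention and variance share", {
  cfg <- sim_config(seed = 11, n_target = 19000, n_discovery = 1000,
                    n_blocks = 10, snps_per_block = 10, ld_decay = 1,
                    n_causal = 40, w_convert_poly = 1.3)
  dm <- gen_ld_genotypes(cfg)
  eff <- plant_effects(dm$variants, cfg)
  i2 <- which(dm$variants$apoe_slot == "e2_site")
  i4 <- which(dm$variants$apoe_slot == "e4_site")
  expect_lt(eff$beta_amyloid[i2], 0)
  expect_gt(eff$beta_amyloid[i4], 0)
  expect_equal(sum(eff$causal), 40L)
  expect_true(all(eff$beta_convert[!eff$causal &
                                     is.na(dm$variants$apoe_slot)] == 0))
  # realized polygenic conversion variance within 10% of configured share
  poly <- eff$beta_convert
  poly[c(i2, i4)] <- 0
  g <- as.numeric(dm$dosages %*% poly)
  expect_lt(abs(var(g) - cfg$w_convert_poly^2) / cfg$w_convert_poly^2, 0.10)
  # no causal effects planted inside the APOE block
  expect_true(all(!eff$causal[dm$variants$block == cfg$apoe_block]))
})

test_that("zero causal variants means no non-APOE effects", {
  cfg <- small_config(seed = 2, n_causal = 0L)
  dm <- gen_ld_genotypes(cfg)
  eff <- plant_effects(dm$variants, cfg)
  expect_true(all(eff$beta_convert[is.na(dm$variants$apoe_slot)] == 0))
  expect_true(all(eff$beta_amyloid[is.na(dm$variants$apoe_slot)] == 0))
})

test_that("amyloid positivity tracks the configured quantile under pure noise", {
  cfg <- small_config(seed = 4, w_amyloid_apoe = 0, w_convert_apoe = 0,
                      w_convert_poly = 0, n_causal = 0L,
                      amyloid_threshold_quantile = 0.7)
  dm <- gen_ld_genotypes(cfg)
  eff <- plant_effects(dm$variants, cfg)
  sim <- gen_two_stage_phenotypes(dm, eff, cfg)
  expect_lt(abs(mean(sim$truth$amyloid_pos) - 0.3), 0.02)
})

test_that("without polygenic effects converters match non-converters on true score", {
  cfg <- sim_config(seed = 9, n_target = 2000, n_discovery = 100,
                    n_blocks = 6, snps_per_block = 10, w_convert_poly = 0,
                    n_causal = 20L)
  dm <- gen_ld_genotypes(cfg)
  eff <- plant_effects(dm$variants, cfg)
  expect_true(all(eff$beta_convert[eff$causal] == 0))
  sim <- gen_two_stage_phenotypes(dm, eff, cfg)
  # score a random non-APOE weighting: converters should not differ
  set.seed(99)
  wpoly <- rnorm(nrow(dm$variants)) *
    as.numeric(is.na(dm$variants$apoe_slot))
  s <- as.numeric(dm$dosages %*% wpoly)
  pos <- sim$truth$amyloid_pos
  dlt <- mean(s[pos & sim$truth$converter]) -
    mean(s[pos & !sim$truth$converter])
  se <- sqrt(var(s[pos & sim$truth$converter]) /
               sum(pos & sim$truth$converter) +
             var(s[pos & !sim$truth$converter]) /
               sum(pos & !sim$truth$converter))
  expect_lt(abs(dlt), 3 * se)
})

test_that("amyloid positivity is enriched in AD relative to controls", {
  cfg <- small_config(seed = 6)
  dm <- gen_ld_genotypes(cfg)
  sim <- gen_two_stage_phenotypes(dm, plant_effects(dm$variants, cfg), cfg)
  labels <- suppressWarnings(classify_trajectory(sim$visits))
  m <- merge(labels, data.frame(IID = sim$truth$iid,
                                pos = sim$truth$amyloid_pos))
  rate <- tapply(m$pos, m$label, mean)
  expect_gt(rate[["AD"]], rate[["CONTROL"]])
})

test_that("SUVR reproduces the 1.11 cutoff at the liability threshold", {
  cfg <- small_config(seed = 12, suvr_missing = 0)
  dm <- gen_ld_genotypes(cfg)
  sim <- gen_two_stage_phenotypes(dm, plant_effects(dm$variants, cfg), cfg)
  expect_identical(sim$truth$suvr >= 1.11, sim$truth$amyloid_pos)
  expect_true(all(sim$truth$age >= 55 & sim$truth$age <= 90))
})

test_that("discovery summary statistics behave as a calibrated score test", {
  cfg <- sim_config(seed = 21, n_target = 100, n_discovery = 10000,
                    n_blocks = 8, snps_per_block = 10, ld_decay = 1,
                    n_causal = 2L, w_convert_poly = 1.5)
  dm <- gen_ld_genotypes(cfg)
  eff <- plant_effects(dm$variants, cfg)
  sim <- gen_two_stage_phenotypes(dm, eff, cfg)
  di <- which(sim$truth$role == "discovery")
  ss <- gen_discovery_sumstats(dm$dosages[di, ], sim$truth$disease[di],
                               dm$variants)
  # definitional p from beta/SE
  expect_equal(ss$P, 2 * pnorm(-abs(ss$BETA / ss$SE)), tolerance = 1e-10)
  # null variants: |z| < 4 in at least 99%
  null_ids <- eff$id[!eff$causal & is.na(dm$variants$apoe_slot)]
  z <- with(ss[ss$SNP %in% null_ids, ], BETA / SE)
  expect_gte(mean(abs(z) < 4), 0.99)
  # planted variants recover their sign
  for (id in eff$id[eff$causal]) {
    expect_equal(sign(ss$BETA[ss$SNP == id]),
                 sign(eff$beta_convert[eff$id == id]))
  }
  expect_error(gen_discovery_sumstats(dm$dosages[di, ],
                                      rep(1L, length(di)), dm$variants),
               "constant")
})

test_that("gene annotation tiles the genome and honors set sizes", {
  cfg <- small_config(seed = 31)
  dm <- gen_ld_genotypes(cfg)
  ann <- gen_gene_annotation(dm$variants, n_sets = 9,
                             set_sizes = c(20, 10, 40, 12, 11, 17, 35, 18, 60),
                             seed = 31)
  expect_length(ann$sets, 9L)
  expect_equal(unname(lengths(ann$sets)),
               c(20, 10, 40, 12, 11, 17, 35, 18, 60))
  # every variant lies in exactly one gene interval
  hits <- vapply(seq_len(nrow(dm$variants)), function(i) {
    sum(ann$genes$chrom == dm$variants$chrom[i] &
          ann$genes$start <= dm$variants$pos[i] &
          ann$genes$end >= dm$variants$pos[i])
  }, numeric(1))
  expect_true(all(hits == 1))
  # the designated set contains the APOE-like gene
  apoe_pos <- dm$variants$pos[match("e4_site", dm$variants$apoe_slot)]
  g <- ann$genes[ann$genes$chrom == "19" & ann$genes$start <= apoe_pos &
                   ann$genes$end >= apoe_pos, "gene"]
  expect_true(g %in% ann$sets[[3]])
})
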