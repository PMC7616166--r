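test_that("identical config and seed reproduce bit-identical data", {
  cfg <- synth_config(n_snps = 40, theta_women = 0.2, n_null_snps = 10,
                      strand_flip_rate = 0.2, allele_swap_rate = 0.2,
                      palindrome_rate = 0.2, seed = 121)
  a <- generate_pair(cfg, "female")
  b <- generate_pair(cfg, "female")
  expect_identical(a$exposure$records, b$exposure$records)
  expect_identical(a$outcome$records, b$outcome$records)
  expect_identical(a$truth, b$truth)
  # male stream differs from female
  m <- generate_pair(cfg, "male")
  expect_false(identical(m$exposure$records$beta, a$exposure$records$beta))
})

test_that("config validation enforces rates, ranges and mandatory seed", {
  expect_error(synth_config(n_snps = 10), "seed is mandatory")
  expect_error(synth_config(eaf_range = c(0.01, 0.9), seed = 1))
  expect_error(synth_config(strand_flip_rate = 1.2, seed = 1))
  expect_error(synth_config(ld_blocks = data.frame(size = 3, r = 0.5),
                            n_snps = 10, seed = 1), "sum to n_snps")
})

test_that("exposure standard errors shrink as n^(-1/2) and strengthen mean F", {
  small <- generate_pair(synth_config(n_snps = 100, n_exposure = 50000,
                                      seed = 122), "female")
  big <- generate_pair(synth_config(n_snps = 100, n_exposure = 800000,
                                    seed = 122), "female")
  expect_equal(small$exposure$records$se / big$exposure$records$se,
               rep(4, 100), tolerance = 1e-12)
  f_small <- suppressWarnings(as.numeric(mean_f_statistic(small$exposure)))
  f_big <- as.numeric(mean_f_statistic(big$exposure))
  expect_gt(f_big, f_small)
})

test_that("null decoys carry no exposure signal and defaults give strong instruments", {
  cfg <- synth_config(n_snps = 150, n_null_snps = 150, seed = 123)
  pair <- generate_pair(cfg, "female")
  truth <- pair$truth$snps
  nulls <- pair$exposure$records[truth$is_null, ]
  # uniform p under the null: none should reach genome-wide significance
  expect_identical(sum(nulls$pvalue <= 5e-8), 0L)
  assoc <- pair$exposure$records[!truth$is_null, ]
  assoc_stats <- summary_stats(assoc, "exp", "SD", "female")
  expect_gt(as.numeric(mean_f_statistic(assoc_stats)), 30)
})

test_that("under no pleiotropy the heterogeneity ratio Q/(J-1) is calibrated", {
  ratios <- vapply(1:60, function(i) {
    cfg <- synth_config(n_snps = 60, theta_women = 0.3, seed = 3000 + i)
    pair <- generate_pair(cfg, "female")
    h <- harmonize(pair$exposure, pair$outcome)
    q <- cochran_q(h, beta = mr_ivw(h, "fixed")$beta)
    q$q / q$df
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 1), 3 * sd(ratios) / sqrt(length(ratios)))
})

test_that("block LD panel has the requested structure and prunes to one SNP per block", {
  blocks <- data.frame(size = rep(5, 10), r = 0.9)
  cfg <- synth_config(n_snps = 50, ld_blocks = blocks, seed = 124)
  panel <- generate_ld_panel(cfg)
  expect_identical(dim(panel$r), c(50L, 50L))
  expect_equal(panel$r[1, 2], 0.9)
  expect_equal(panel$r[1, 6], 0)
  expect_equal(unname(diag(panel$r)), rep(1, 50))
  pair <- generate_pair(cfg, "female")
  kept <- clump(pair$exposure, panel, r2_threshold = 0.001, p_threshold = 1)
  expect_identical(nrow(kept$records), 10L)
  # exactly the per-block p-minima survive
  blk <- rep(1:10, each = 5)
  pv <- pair$exposure$records$pvalue
  best <- vapply(1:10, function(b) {
    ids <- pair$exposure$records$rsid[blk == b]
    ids[which.min(pv[blk == b])]
  }, character(1))
  expect_setequal(kept$records$rsid, best)
})

test_that("near-threshold LD blocks are not pruned; non-PD blocks error", {
  blocks <- data.frame(size = rep(5, 4), r = 0.03)  # r^2 = 9e-4 < 1e-3
  cfg <- synth_config(n_snps = 20, ld_blocks = blocks, seed = 125)
  panel <- generate_ld_panel(cfg)
  pair <- generate_pair(cfg, "female")
  kept <- clump(pair$exposure, panel, r2_threshold = 0.001, p_threshold = 1)
  expect_identical(nrow(kept$records), 20L)
  bad <- synth_config(n_snps = 4,
                      ld_blocks = data.frame(size = 4, r = -0.5), seed = 1)
  expect_error(generate_ld_panel(bad), "non-positive-definite")
})

test_that("a null causal effect is recovered as such by IVW", {
  cfg <- synth_config(n_snps = 150, theta_women = 0, seed = 126)
  pair <- generate_pair(cfg, "female")
  h <- harmonize(pair$exposure, pair$outcome)
  fit <- mr_ivw(h)
  expect_lt(abs(fit$beta), 3 * fit$se)
})

test_that("directional pleiotropy surfaces in the Egger intercept", {
  cfg <- synth_config(n_snps = 300, theta_women = 0.3,
                      pleiotropy_mode = "directional", pleiotropy_mean = 0.1,
                      pleiotropy_sd = 0.02, seed = 127)
  pair <- generate_pair(cfg, "female")
  h <- harmonize(filter_pvalue(pair$exposure), pair$outcome)
  eg <- mr_egger(h)
  expect_lt(abs(eg$egger_intercept - 0.1), 3 * eg$egger_intercept_se)
  expect_lte(eg$egger_intercept_p, 0.05)
})
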