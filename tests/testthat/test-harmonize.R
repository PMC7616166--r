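two_study <- function(ex_alleles, ou_alleles, beta_y = -0.05,
                      eaf_x = 0.2, eaf_y = 0.2) {
  ex <- make_stats(1, effect_allele = ex_alleles[1], other_allele = ex_alleles[2],
                   beta = 0.10, eaf = eaf_x, trait = "exp", sex = "female")
  ou <- make_stats(1, effect_allele = ou_alleles[1], other_allele = ou_alleles[2],
                   beta = beta_y, eaf = eaf_y, trait = "out", sex = "female")
  harmonize(ex, ou)
}

test_that("allele orientation rules: identical, swapped, strand-complement", {
  expect_equal(two_study(c("A", "G"), c("A", "G"))$beta_y, -0.05)
  # swapped alleles: outcome beta negated
  expect_equal(two_study(c("A", "G"), c("G", "A"))$beta_y, 0.05)
  # strand complement of the same orientation: unchanged
  expect_equal(two_study(c("A", "G"), c("T", "C"))$beta_y, -0.05)
  # strand complement of the swapped orientation: negated
  expect_equal(two_study(c("A", "G"), c("C", "T"))$beta_y, 0.05)
  # exposure beta never altered
  expect_equal(two_study(c("A", "G"), c("G", "A"))$beta_x, 0.10)
  # irreconcilable alleles dropped
  h <- two_study(c("A", "G"), c("A", "C"))
  expect_identical(nrow(h$dropped), 1L)
  expect_identical(h$dropped$reason, "allele mismatch")
})

test_that("palindromic variants: ambiguity window and frequency orientation", {
  # MAF at 0.5: ambiguous for any positive window
  h <- two_study(c("A", "T"), c("A", "T"), eaf_x = 0.5, eaf_y = 0.5)
  expect_identical(h$dropped$reason, "ambiguous palindrome")
  # MAF just inside the default window boundary (0.42) is also dropped
  h2 <- two_study(c("A", "T"), c("A", "T"), eaf_x = 0.45, eaf_y = 0.45)
  expect_identical(h2$dropped$reason, "ambiguous palindrome")
  # clear frequencies, same side of 0.5: kept as-is
  h3 <- two_study(c("G", "C"), c("C", "G"), eaf_x = 0.2, eaf_y = 0.22)
  expect_equal(h3$beta_y, -0.05)
  # opposite sides of 0.5: outcome flipped
  h4 <- two_study(c("G", "C"), c("G", "C"), eaf_x = 0.2, eaf_y = 0.8)
  expect_equal(h4$beta_y, 0.05)
  expect_equal(h4$eaf_y, 0.2)
})

test_that("every shared SNP lands in exactly one of retained or dropped", {
  cfg <- synth_config(n_snps = 80, theta_women = 0.3, n_null_snps = 20,
                      strand_flip_rate = 0.3, allele_swap_rate = 0.3,
                      palindrome_rate = 0.3, seed = 21)
  pair <- generate_pair(cfg, "female")
  h <- harmonize(pair$exposure, pair$outcome)
  shared <- intersect(pair$exposure$records$rsid, pair$outcome$records$rsid)
  expect_identical(length(h$rsids) + nrow(h$dropped), length(shared))
  expect_identical(sort(c(h$rsids, h$dropped$rsid)), sort(shared))
  expect_identical(anyDuplicated(c(h$rsids, h$dropped$rsid)), 0L)
})

test_that("empty rsid intersection is a hard error", {
  ex <- make_stats(2, rsid = c("rs1", "rs2"), sex = "female")
  ou <- make_stats(2, rsid = c("rs3", "rs4"), sex = "female")
  expect_error(harmonize(ex, ou), "no shared rsids")
})

test_that("harmonizing an already-aligned outcome is a no-op (involution)", {
  cfg <- synth_config(n_snps = 50, theta_women = 0.4,
                      strand_flip_rate = 0.4, allele_swap_rate = 0.4,
                      seed = 22)
  pair <- generate_pair(cfg, "female")
  h1 <- harmonize(pair$exposure, pair$outcome)
  ex_rec <- pair$exposure$records
  aligned <- ex_rec[match(h1$rsids, ex_rec$rsid), ]
  aligned$beta <- h1$beta_y
  aligned$se <- h1$se_y
  aligned$eaf <- h1$eaf_y
  realigned <- summary_stats(aligned, trait = "out", unit = "log-odds",
                             sex = "female")
  h2 <- harmonize(pair$exposure, realigned)
  expect_identical(h2$beta_y, h1$beta_y)
  expect_identical(nrow(h2$dropped), 0L)
})

test_that("harmonization recovers generated outcome effects exactly despite corruption", {
  cfg <- synth_config(n_snps = 120, theta_women = 0.5,
                      strand_flip_rate = 0.25, allele_swap_rate = 0.25,
                      palindrome_rate = 0.2, seed = 23)
  pair <- generate_pair(cfg, "female")
  h <- harmonize(pair$exposure, pair$outcome)
  truth <- pair$truth$snps
  recovered <- h$beta_y
  expected <- truth$beta_y[match(h$rsids, truth$rsid)]
  expect_identical(recovered, expected)
  # only palindromes near 0.5 may be dropped here
  if (nrow(h$dropped)) {
    expect_true(all(h$dropped$reason == "ambiguous palindrome"))
    expect_true(all(truth$palindromic[match(h$dropped$rsid, truth$rsid)]))
  }
})

test_that("sign coherence survives random allele relabelling", {
  for (seed in 24:26) {
    cfg <- synth_config(n_snps = 100, theta_women = 0.6,
                        strand_flip_rate = 0.5, allele_swap_rate = 0.5,
                        seed = seed)
    pair <- generate_pair(cfg, "female")
    h <- harmonize(pair$exposure, pair$outcome)
    expect_gt(cor(h$beta_x, h$beta_y), 0)
  }
})
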