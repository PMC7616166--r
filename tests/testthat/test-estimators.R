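test_that("per-SNP Wald ratios use the first-order delta SE", {
  h <- make_h(beta_x = 0.5, beta_y = 0.25, se_x = 0.05, se_y = 0.10)
  r <- ratio_estimates(h)
  expect_equal(r$ratio, 0.5)
  expect_equal(r$ratio_se, 0.2)
  h0 <- make_h(beta_x = c(0.5, 0.4), beta_y = c(0, 0.2), se_y = c(0.1, 0.1))
  r0 <- ratio_estimates(h0)
  expect_equal(r0$ratio[1], 0)
  expect_equal(r0$ratio_se[1], 0.2)
  hz <- make_h(beta_x = c(0.5, 0), beta_y = c(0.25, 0.1))
  expect_warning(rz <- ratio_estimates(hz), "beta_x = 0")
  expect_identical(rz$rsid, "rs1")
})

test_that("first-order ratio SE matches Monte-Carlo spread for strong instruments", {
  set.seed(41)
  bx <- 0.3; sx <- 0.02; by <- 0.15; sy <- 0.05  # |bx/sx| = 15
  draws <- rnorm(1e5, by, sy) / rnorm(1e5, bx, sx)
  mc_sd <- sd(draws)
  delta <- sy / abs(bx)
  expect_lt(abs(delta - mc_sd) / mc_sd, 0.10)
})

test_that("IVW on a single SNP is the Wald ratio; two-SNP case matches closed form", {
  h1 <- make_h(beta_x = 0.5, beta_y = 0.25, se_x = 0.05, se_y = 0.10)
  expect_warning(est <- mr_ivw(h1), "single SNP")
  expect_equal(est$beta, 0.5)
  expect_equal(est$se, 0.2)
  h2 <- make_h(beta_x = c(0.1, 0.2), beta_y = c(0.05, 0.10), se_y = c(0.01, 0.01))
  est2 <- mr_ivw(h2)
  expect_equal(est2$beta, 0.5)
  expect_equal(est2$q_stat, 0)
  expect_equal(est2$se, (1e4 * 0.05)^(-1 / 2))  # Q = 0: random = fixed
  expect_equal(est2$or, exp(est2$beta))
})

test_that("IVW slope equals the weighted-least-squares oracle on random instances", {
  for (seed in 42:61) {
    h <- random_h(J = sample(5:40, 1), seed = seed)
    fit <- mr_ivw(h, model = "fixed")
    oracle <- lm(h$beta_y ~ 0 + h$beta_x, weights = 1 / h$se_y^2)
    expect_lt(abs(fit$beta - unname(coef(oracle))), 1e-10)
    # fixed-effect SE equals the unit-variance WLS slope SE
    se_oracle <- summary(oracle)$coefficients[1, 2] / summary(oracle)$sigma
    expect_lt(abs(fit$se - se_oracle), 1e-10)
  }
})

test_that("multiplicative random-effects SE never deflates below fixed", {
  for (seed in 62:71) {
    h <- random_h(J = 15, seed = seed)
    expect_gte(mr_ivw(h, "random")$se, mr_ivw(h, "fixed")$se)
  }
})

test_that("Egger matches the free-intercept WLS oracle when residuals are overdispersed", {
  set.seed(72)
  J <- 25
  bx <- abs(rnorm(J, 0.1, 0.04))
  by <- 0.3 * bx + 0.05 + rnorm(J, 0, 0.05)  # gross heterogeneity: Q/(J-2) > 1
  h <- make_h(bx, by, se_y = rep(0.01, J))
  fit <- mr_egger(h)
  oracle <- lm(by ~ bx, weights = rep(1e4, J))
  co <- summary(oracle)$coefficients
  expect_gt(summary(oracle)$sigma, 1)  # inflation active: SEs comparable
  expect_equal(fit$egger_intercept, unname(co[1, 1]), tolerance = 1e-10)
  expect_equal(fit$beta, unname(co[2, 1]), tolerance = 1e-10)
  expect_equal(fit$egger_intercept_se, unname(co[1, 2]), tolerance = 1e-8)
  expect_equal(fit$se, unname(co[2, 2]), tolerance = 1e-8)
})

test_that("Egger recovers slope and directional intercept from simulated pleiotropy", {
  hits <- 0L
  reps <- 50
  for (i in seq_len(reps)) {
    cfg <- synth_config(n_snps = 200, theta_women = 0.3,
                        pleiotropy_mode = "directional",
                        pleiotropy_mean = 0.1, pleiotropy_sd = 0.02,
                        seed = 100 + 2 * i)
    pair <- generate_pair(cfg, "female")
    # estimation sits downstream of instrument selection
    h <- harmonize(filter_pvalue(pair$exposure), pair$outcome)
    fit <- mr_egger(h)
    in3 <- abs(fit$egger_intercept - 0.1) < 3 * fit$egger_intercept_se &&
           abs(fit$beta - 0.3) < 3 * fit$se
    hits <- hits + in3
  }
  expect_gte(hits / reps, 0.9)
})

test_that("Egger intercept test holds its size under balanced pleiotropy", {
  set.seed(73)
  rej <- 0L
  reps <- 300
  for (i in seq_len(reps)) {
    J <- 30
    bx <- abs(rnorm(J, 0.1, 0.03))
    alpha <- rnorm(J, 0, 0.02)  # balanced: zero mean
    by <- 0.2 * bx + alpha + rnorm(J, 0, 0.005)
    h <- make_h(bx, by, se_y = rep(0.005, J))
    rej <- rej + (mr_egger(h)$egger_intercept_p <= 0.05)
  }
  # binomial 3-sigma band around 0.05
  expect_lt(abs(rej / reps - 0.05), 3 * sqrt(0.05 * 0.95 / reps))
})

test_that("Egger requires spread in the oriented exposure effects", {
  h <- make_h(beta_x = c(0.1, 0.1, -0.1, 0.1), beta_y = c(0.05, 0.03, 0.04, 0.06))
  expect_error(mr_egger(h), "Egger unidentified")
})

test_that("median estimators: interpolation, degenerate weights, equal-weight identity", {
  # equal weights, ratios {0.2, 0.5, 0.9}: cumulative midpoint hits 0.5 at rs2
  h <- make_h(beta_x = c(1, 1, 1), beta_y = c(0.2, 0.5, 0.9),
              se_y = c(0.1, 0.1, 0.1))
  est <- mr_median(h, weighted = FALSE, n_boot = 200, seed = 1)
  expect_equal(est$beta, 0.5)
  # nearly all weight on one SNP pins the estimate to its ratio
  hw <- make_h(beta_x = c(1, 1, 1), beta_y = c(0.2, 0.5, 0.9),
               se_y = c(1, 1e-4, 1))
  expect_equal(mr_median(hw, weighted = TRUE, n_boot = 200, seed = 1)$beta, 0.5,
               tolerance = 1e-6)
  # equal ratio SEs make the weighted and simple medians identical
  he <- make_h(beta_x = rep(1, 5), beta_y = c(0.1, 0.4, 0.3, 0.8, 0.2),
               se_y = rep(0.05, 5))
  expect_equal(mr_median(he, weighted = TRUE, n_boot = 100, seed = 2)$beta,
               mr_median(he, weighted = FALSE, n_boot = 100, seed = 2)$beta,
               tolerance = 1e-12)
  expect_warning(mr_median(he, n_boot = 50, seed = 1), "n_boot < 100")
  expect_error(mr_median(he, n_boot = 100), "seed is mandatory")
})

test_that("median bootstrap SE is reproducible and scales sensibly", {
  h <- random_h(12, seed = 81)
  a <- mr_median(h, n_boot = 500, seed = 9)
  b <- mr_median(h, n_boot = 500, seed = 9)
  expect_identical(a$se, b$se)
  expect_gt(a$se, 0)
})

test_that("every estimator is invariant to flipping both betas of a SNP", {
  h <- random_h(15, seed = 82)
  h2 <- h
  flip <- c(1, 4, 7)
  h2$beta_x[flip] <- -h2$beta_x[flip]
  h2$beta_y[flip] <- -h2$beta_y[flip]
  expect_equal(mr_ivw(h)$beta, mr_ivw(h2)$beta, tolerance = 1e-14)
  expect_equal(mr_ivw(h)$se, mr_ivw(h2)$se, tolerance = 1e-14)
  expect_equal(mr_egger(h)[c("beta", "se", "egger_intercept")],
               mr_egger(h2)[c("beta", "se", "egger_intercept")],
               tolerance = 1e-14)
  expect_identical(mr_median(h, n_boot = 300, seed = 5)$beta,
                   mr_median(h2, n_boot = 300, seed = 5)$beta)
  expect_identical(mr_median(h, n_boot = 300, seed = 5)$se,
                   mr_median(h2, n_boot = 300, seed = 5)$se)
  expect_equal(cochran_q(h)$q, cochran_q(h2)$q, tolerance = 1e-14)
})

test_that("Egger slope equals IVW when the fitted intercept is zero by construction", {
  # symmetric design: weighted means of bx-residual times by vanish
  bx <- c(0.1, 0.2, 0.3)
  by <- 0.4 * bx  # exact proportionality: intercept exactly 0
  h <- make_h(bx, by, se_y = rep(0.01, 3))
  eg <- mr_egger(h)
  expect_equal(eg$egger_intercept, 0, tolerance = 1e-12)
  expect_equal(eg$beta, mr_ivw(h, "fixed")$beta, tolerance = 1e-12)
})

test_that("Cochran's Q: zero under proportionality, calibrated under homogeneity, inflated by outliers", {
  h <- make_h(beta_x = c(0.1, 0.2, 0.4), beta_y = c(0.03, 0.06, 0.12),
              se_y = rep(0.01, 3))
  q <- cochran_q(h)
  expect_equal(q$q, 0, tolerance = 1e-20)
  expect_equal(q$pvalue, 1)
  # homogeneous simulation: Q/(J-1) has mean 1
  set.seed(83)
  ratios <- replicate(300, {
    J <- 10
    bx <- abs(rnorm(J, 0.1, 0.03))
    by <- 0.3 * bx + rnorm(J, 0, 0.01)
    cochran_q(make_h(bx, by, se_y = rep(0.01, J)))$q / (J - 1)
  })
  expect_lt(abs(mean(ratios) - 1), 3 * sd(ratios) / sqrt(length(ratios)))
  # one gross outlier pushes Q past the 0.999 quantile
  bx <- abs(rnorm(20, 0.1, 0.03))
  by <- 0.3 * bx + rnorm(20, 0, 0.01)
  by[7] <- by[7] + 0.2
  qo <- cochran_q(make_h(bx, by, se_y = rep(0.01, 20)))
  expect_gt(qo$q, qchisq(0.999, df = 19))
})
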