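# Small builders used across the suite. All fixtures are generated in code.

# minimal valid record table; any column overridable
make_records <- function(n = 3, ...) {
  out <- data.frame(
    rsid = sprintf("rs%d", seq_len(n)),
    chrom = "1",
    pos = seq_len(n) * 1000L,
    effect_allele = rep_len(c("A", "C", "G"), n),
    other_allele = rep_len(c("G", "T", "A"), n),
    eaf = rep_len(c(0.2, 0.4, 0.3), n),
    beta = rep_len(c(0.1, -0.05, 0.2), n),
    se = rep_len(0.02, n),
    pvalue = rep_len(c(1e-9, 1e-10, 1e-12), n),
    n = 10000L,
    stringsAsFactors = FALSE
  )
  override <- list(...)
  for (nm in names(override)) out[[nm]] <- override[[nm]]
  out
}

make_stats <- function(n = 3, ..., trait = "exposure", unit = "SD",
                       sex = "combined") {
  summary_stats(make_records(n, ...), trait = trait, unit = unit, sex = sex)
}

make_h <- function(beta_x, beta_y, se_x = rep(0.01, length(beta_x)),
                   se_y = rep(0.01, length(beta_x))) {
  harmonized_instruments(
    rsids = sprintf("rs%d", seq_along(beta_x)),
    beta_x = beta_x, se_x = se_x, beta_y = beta_y, se_y = se_y)
}

# random heterogeneous instrument set for oracle comparisons
random_h <- function(J, seed) {
  set.seed(seed)
  make_h(beta_x = rnorm(J, 0.1, 0.05),
         beta_y = rnorm(J, 0.03, 0.02),
         se_x = runif(J, 0.005, 0.02),
         se_y = runif(J, 0.005, 0.03))
}
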