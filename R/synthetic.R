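#' Configuration for the synthetic GWAS summary-statistics generator
#'
#' Bundles the ground-truth generative parameters for a sex-stratified
#' two-sample MR simulation: per-sex causal effects, instrument strength,
#' pleiotropy, LD block structure, decoy null variants, and the allele
#' representation corruptions (strand flips, effect/other swaps,
#' palindromic variants) that exercise harmonization.
#'
#' Default sample sizes emulate a consortium-scale exposure GWAS
#' (n = 250000) feeding a case-control outcome GWAS of tens of thousands
#' (n = 80000); with `beta_x_sd = 0.025` the implied mean per-SNP
#' F-statistic is around 65, inside the 37-245 range typical of published
#' sex-specific cardiometabolic instruments.
#'
#' @param n_snps number of truly associated SNPs.
#' @param theta_women,theta_men true causal effects (log-odds per exposure
#'   unit).
#' @param n_exposure,n_outcome GWAS sample sizes.
#' @param eaf_range interval for effect-allele frequencies, within
#'   (0.05, 0.95).
#' @param beta_x_sd scale of the true SNP-exposure effect magnitudes (drawn
#'   half-normal, with the effect allele coded as the exposure-increasing
#'   allele).
#' @param pleiotropy_mode `"none"`, `"balanced"` (zero-mean direct effects)
#'   or `"directional"` (mean `pleiotropy_mean`).
#' @param pleiotropy_sd,pleiotropy_mean pleiotropic effect distribution.
#' @param ld_blocks optional data.frame with columns `size`, `r` describing
#'   consecutive equicorrelated LD blocks over the associated SNPs;
#'   sizes must sum to `n_snps`.
#' @param n_null_snps decoy variants with no exposure association.
#' @param strand_flip_rate,allele_swap_rate,palindrome_rate probabilities of
#'   the respective allele-representation corruptions in the outcome file.
#' @param seed integer seed; mandatory.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_snps = 150L,
                         theta_women = 0, theta_men = 0,
                         n_exposure = 250000L, n_outcome = 80000L,
                         eaf_range = c(0.1, 0.9),
                         beta_x_sd = 0.025,
                         pleiotropy_mode = c("none", "balanced", "directional"),
                         pleiotropy_sd = 0.02, pleiotropy_mean = 0.1,
                         ld_blocks = NULL,
                         n_null_snps = 0L,
                         strand_flip_rate = 0, allele_swap_rate = 0,
                         palindrome_rate = 0,
                         seed) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(n_snps >= 1, n_exposure > 1, n_outcome > 1,
            length(eaf_range) == 2L, eaf_range[1] < eaf_range[2],
            eaf_range[1] >= 0.05, eaf_range[2] <= 0.95,
            beta_x_sd > 0, pleiotropy_sd >= 0, n_null_snps >= 0)
  for (rate in c(strand_flip_rate, allele_swap_rate, palindrome_rate)) {
    stopifnot(rate >= 0, rate <= 1)
  }
  if (!is.null(ld_blocks)) {
    stopifnot(is.data.frame(ld_blocks), all(c("size", "r") %in% names(ld_blocks)))
    if (sum(ld_blocks$size) != n_snps) {
      stop("ld_blocks sizes must sum to n_snps", call. = FALSE)
    }
  }
  structure(
    list(n_snps = as.integer(n_snps),
         theta_women = theta_women, theta_men = theta_men,
         n_exposure = as.integer(n_exposure), n_outcome = as.integer(n_outcome),
         eaf_range = eaf_range, beta_x_sd = beta_x_sd,
         pleiotropy_mode = pleiotropy_mode,
         pleiotropy_sd = pleiotropy_sd, pleiotropy_mean = pleiotropy_mean,
         ld_blocks = ld_blocks, n_null_snps = as.integer(n_null_snps),
         strand_flip_rate = strand_flip_rate,
         allele_swap_rate = allele_swap_rate,
         palindrome_rate = palindrome_rate,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

NONPAL_PAIRS <- rbind(c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
                      c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G"))
PAL_PAIRS <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))

#' Generate a synthetic two-sample GWAS summary-statistics pair
#'
#' Simulates, on the summary-statistic scale, an exposure GWAS and an
#' outcome GWAS for one sex with known ground truth. True per-SNP exposure
#' effect magnitudes are half-normal with scale `beta_x_sd` (the effect
#' allele is coded as the exposure-increasing allele); observed exposure
#' effects add sampling noise with `se_x = (2 eaf (1-eaf) n_exposure)^-1/2`,
#' and analogously for the outcome with `n_outcome`. Outcome effects are
#' centred at `theta_sex * b + alpha` where `alpha` is zero, zero-mean
#' normal, or directional normal per the pleiotropy mode. Wald p-values are
#' two-sided. Decoy null SNPs (no exposure effect) are appended, and the
#' outcome file's allele representation is corrupted at the configured
#' swap/strand-flip rates (a pure change of representation: harmonization
#' must recover the generated effects exactly for non-ambiguous variants).
#'
#' @param config a [synth_config].
#' @param sex `"female"` or `"male"`; selects the causal effect and offsets
#'   the stream of random numbers so the two sexes are independent draws.
#' @param trait,outcome_trait trait labels for the generated files.
#' @return list with elements `exposure` and `outcome` ([summary_stats])
#'   and `truth` (list: `theta`, per-SNP data.frame `snps` with the
#'   generative quantities and corruption flags).
#' @export
generate_pair <- function(config, sex = c("female", "male"),
                          trait = "exposure", outcome_trait = "outcome") {
  stopifnot(inherits(config, "synth_config"))
  sex <- match.arg(sex)
  theta <- if (sex == "female") config$theta_women else config$theta_men
  n_assoc <- config$n_snps
  n_tot <- n_assoc + config$n_null_snps
  seed <- config$seed + if (sex == "female") 0L else 1L

  withr_seed(seed, {
    rsid <- sprintf("rs%05d", seq_len(n_tot))
    eaf <- stats::runif(n_tot, config$eaf_range[1], config$eaf_range[2])
    b_true <- c(abs(stats::rnorm(n_assoc, 0, config$beta_x_sd)),
                rep(0, config$n_null_snps))
    alpha <- switch(config$pleiotropy_mode,
      none = rep(0, n_tot),
      balanced = stats::rnorm(n_tot, 0, config$pleiotropy_sd),
      directional = stats::rnorm(n_tot, config$pleiotropy_mean,
                                 config$pleiotropy_sd))
    alpha[b_true == 0] <- 0
    se_x <- 1 / sqrt(2 * eaf * (1 - eaf) * config$n_exposure)
    se_y <- 1 / sqrt(2 * eaf * (1 - eaf) * config$n_outcome)
    beta_x <- stats::rnorm(n_tot, b_true, se_x)
    beta_y <- stats::rnorm(n_tot, theta * b_true + alpha, se_y)

    pal <- stats::runif(n_tot) < config$palindrome_rate
    pick <- function(pairs, k) pairs[sample.int(nrow(pairs), k, replace = TRUE), ,
                                     drop = FALSE]
    alleles <- matrix("", n_tot, 2)
    if (any(pal)) alleles[pal, ] <- pick(PAL_PAIRS, sum(pal))
    if (any(!pal)) alleles[!pal, ] <- pick(NONPAL_PAIRS, sum(!pal))

    swap <- stats::runif(n_tot) < config$allele_swap_rate
    flip <- stats::runif(n_tot) < config$strand_flip_rate

    make_stats <- function(beta, se, n, trait_name, alleles, eaf) {
      p <- 2 * stats::pnorm(-abs(beta / se))
      summary_stats(
        data.frame(rsid = rsid, chrom = "1", pos = seq_len(n_tot) * 1000L,
                   effect_allele = alleles[, 1], other_allele = alleles[, 2],
                   eaf = eaf, beta = beta, se = se, pvalue = pmax(p, 1e-320),
                   n = n, stringsAsFactors = FALSE),
        trait = trait_name, unit = "SD", sex = sex)
    }

    exposure <- make_stats(beta_x, se_x, config$n_exposure, trait, alleles, eaf)

    # corrupt the outcome's allele representation: a swap restates the
    # association for the other allele; a strand flip relabels to the
    # complementary strand. Palindromic variants ignore swaps (their flipped
    # labels are indistinguishable anyway; frequency carries the signal).
    all_y <- alleles
    beta_y_rep <- beta_y
    eaf_y <- eaf
    do_swap <- swap & !pal
    all_y[do_swap, ] <- all_y[do_swap, c(2, 1), drop = FALSE]
    beta_y_rep[do_swap] <- -beta_y_rep[do_swap]
    eaf_y[do_swap] <- 1 - eaf_y[do_swap]
    all_y[flip, ] <- matrix(COMPLEMENT[all_y[flip, , drop = FALSE]], ncol = 2)
    outcome <- make_stats(beta_y_rep, se_y, config$n_outcome, outcome_trait,
                          all_y, eaf_y)

    truth <- list(
      theta = theta, sex = sex, seed = seed,
      snps = data.frame(rsid = rsid, eaf = eaf, b_true = b_true,
                        alpha = alpha, beta_x = beta_x, beta_y = beta_y,
                        se_x = se_x, se_y = se_y,
                        is_null = b_true == 0, palindromic = pal,
                        swapped = do_swap, flipped = flip,
                        stringsAsFactors = FALSE))
    list(exposure = exposure, outcome = outcome, truth = truth)
  })
}

#' Generate the LD reference panel matching a synthetic configuration
#'
#' Builds a block-diagonal correlation matrix: consecutive equicorrelated
#' blocks (per `config$ld_blocks`) over the associated SNPs, identity for
#' the decoy null SNPs. Without `ld_blocks`, all SNPs are uncorrelated.
#'
#' @param config a [synth_config].
#' @return An [ld_panel] covering all generated SNPs.
#' @export
generate_ld_panel <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  n_tot <- config$n_snps + config$n_null_snps
  rsid <- sprintf("rs%05d", seq_len(n_tot))
  r <- diag(n_tot)
  if (!is.null(config$ld_blocks)) {
    at <- 1L
    for (i in seq_len(nrow(config$ld_blocks))) {
      m <- config$ld_blocks$size[i]
      rho <- config$ld_blocks$r[i]
      if (m > 1 && (rho <= -1 / (m - 1) || rho >= 1)) {
        stop(sprintf("ld block %d: r = %g gives a non-positive-definite block",
                     i, rho), call. = FALSE)
      }
      idx <- at:(at + m - 1L)
      blk <- matrix(rho, m, m)
      diag(blk) <- 1
      r[idx, idx] <- blk
      at <- at + m
    }
  }
  ld_panel(rsid, r)
}
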