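#' Per-SNP Wald ratio estimates
#'
#' The building block of the median estimators: `ratio = beta_y / beta_x`
#' with first-order (delta-method) standard error `se_y / |beta_x|`. SNPs
#' with `beta_x == 0` are excluded with a warning.
#'
#' @param h a [harmonized_instruments] object.
#' @return data.frame with columns `rsid`, `ratio`, `ratio_se`.
#' @export
ratio_estimates <- function(h) {
  stopifnot(inherits(h, "harmonized_instruments"))
  zero <- h$beta_x == 0
  if (any(zero)) {
    warning(sprintf("%d SNP(s) with beta_x = 0 excluded from ratio estimates: %s",
                    sum(zero), paste(h$rsids[zero], collapse = ", ")),
            call. = FALSE)
  }
  data.frame(rsid = h$rsids[!zero],
             ratio = h$beta_y[!zero] / h$beta_x[!zero],
             ratio_se = h$se_y[!zero] / abs(h$beta_x[!zero]),
             stringsAsFactors = FALSE)
}

Z975 <- stats::qnorm(0.975)

# Assembles one estimate row on the log-odds scale; CI and p from the
# standard normal (summary-data MR convention, not t).
mr_estimate <- function(method, beta, se, n, q_stat = NA_real_,
                        egger_intercept = NA_real_,
                        egger_intercept_se = NA_real_,
                        egger_intercept_p = NA_real_) {
  structure(
    list(method = method, beta = beta, se = se,
         or = exp(beta),
         ci_low = exp(beta - Z975 * se), ci_high = exp(beta + Z975 * se),
         pvalue = 2 * stats::pnorm(-abs(beta / se)),
         n_snps = n, q_stat = q_stat,
         egger_intercept = egger_intercept,
         egger_intercept_se = egger_intercept_se,
         egger_intercept_p = egger_intercept_p),
    class = "mr_estimate"
  )
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%s: OR %.3f (95%% CI %.3f, %.3f), p = %.3g [%d SNPs]\n",
              x$method, x$or, x$ci_low, x$ci_high, x$pvalue, x$n_snps))
  if (!is.na(x$egger_intercept)) {
    cat(sprintf("  intercept %.4f (se %.4f), p = %.3g\n",
                x$egger_intercept, x$egger_intercept_se, x$egger_intercept_p))
  }
  invisible(x)
}

#' Inverse-variance-weighted causal estimate
#'
#' Weighted regression of the SNP-outcome effects on the SNP-exposure effects
#' through the origin with weights `1/se_y^2`:
#' `beta = sum(w * bx * by) / sum(w * bx^2)`, fixed-effect standard error
#' `(sum(w * bx^2))^(-1/2)`. Under the default multiplicative random-effects
#' model the standard error is inflated by `max(1, sqrt(Q / (J - 1)))`, where
#' Q is Cochran's heterogeneity statistic at the fitted slope; the inflation
#' never deflates below the fixed-effect value.
#'
#' @param h a [harmonized_instruments] object with at least one SNP.
#' @param model `"random"` (multiplicative random effects, default) or
#'   `"fixed"`. A single SNP forces the fixed model with a warning.
#' @return An `mr_estimate` (method `"ivw"`) including `q_stat`.
#' @export
mr_ivw <- function(h, model = c("random", "fixed")) {
  stopifnot(inherits(h, "harmonized_instruments"))
  model <- match.arg(model)
  J <- n_snps(h)
  if (J < 1) stop("IVW requires at least one SNP", call. = FALSE)
  w <- 1 / h$se_y^2
  denom <- sum(w * h$beta_x^2)
  beta <- sum(w * h$beta_x * h$beta_y) / denom
  se <- sqrt(1 / denom)
  q <- sum(w * (h$beta_y - beta * h$beta_x)^2)
  if (model == "random") {
    if (J == 1) {
      warning("single SNP: falling back to fixed-effect IVW", call. = FALSE)
    } else {
      se <- se * max(1, sqrt(q / (J - 1)))
    }
  }
  mr_estimate("ivw", beta, se, J, q_stat = q)
}

#' MR-Egger regression
#'
#' Weighted linear regression of the SNP-outcome effects on the SNP-exposure
#' effects with a free intercept (weights `1/se_y^2`), after orienting every
#' SNP so its exposure effect is non-negative. The slope is the causal
#' estimate under the InSIDE assumption; a non-zero intercept indicates
#' directional pleiotropy and is reported with its own standard error and
#' p-value. Standard errors carry the multiplicative residual inflation
#' `max(1, sqrt(Q_egger / (J - 2)))`.
#'
#' @param h a [harmonized_instruments] object with at least three SNPs.
#' @return An `mr_estimate` (method `"egger"`) with intercept fields.
#' @export
mr_egger <- function(h) {
  stopifnot(inherits(h, "harmonized_instruments"))
  J <- n_snps(h)
  if (J < 3) stop("MR-Egger requires at least 3 SNPs", call. = FALSE)
  flip <- h$beta_x < 0
  bx <- ifelse(flip, -h$beta_x, h$beta_x)
  by <- ifelse(flip, -h$beta_y, h$beta_y)
  if (max(bx) - min(bx) < .Machine$double.eps^0.5 * max(abs(bx), 1)) {
    stop("Egger unidentified: no spread in oriented exposure effects",
         call. = FALSE)
  }
  w <- 1 / h$se_y^2
  # weighted normal equations for (intercept, slope)
  sw <- sum(w); swx <- sum(w * bx); swx2 <- sum(w * bx^2)
  swy <- sum(w * by); swxy <- sum(w * bx * by)
  det <- sw * swx2 - swx^2
  intercept <- (swx2 * swy - swx * swxy) / det
  slope <- (sw * swxy - swx * swy) / det
  q <- sum(w * (by - intercept - slope * bx)^2)
  infl <- max(1, sqrt(q / (J - 2)))
  se_slope <- sqrt(sw / det) * infl
  se_int <- sqrt(swx2 / det) * infl
  mr_estimate("egger", slope, se_slope, J, q_stat = q,
              egger_intercept = intercept,
              egger_intercept_se = se_int,
              egger_intercept_p = 2 * stats::pnorm(-abs(intercept / se_int)))
}

# Weighted median of per-SNP ratios by the cumulative-midpoint construction:
# with ratios sorted ascending and normalized weights w', the running
# midpoint s_j = cumsum(w')_j - w'_j/2 is mapped against 0.5 and the ratio
# is linearly interpolated between the straddling SNPs.
weighted_median_point <- function(ratio, weight) {
  ord <- order(ratio)
  r <- ratio[ord]
  wp <- weight[ord] / sum(weight)
  s <- cumsum(wp) - wp / 2
  if (0.5 <= s[1L]) return(r[1L])
  if (0.5 >= s[length(s)]) return(r[length(r)])
  below <- max(which(s <= 0.5))
  if (s[below] == 0.5) return(r[below])
  r[below] + (r[below + 1L] - r[below]) * (0.5 - s[below]) / (s[below + 1L] - s[below])
}

#' Median-based causal estimates
#'
#' The weighted median is the 50th percentile of the weight-ordered per-SNP
#' Wald ratios (inverse-variance weights `ratio_se^-2`), linearly
#' interpolated at the cumulative-midpoint 0.5; it is consistent when at
#' least half the weight comes from valid instruments. The simple median is
#' the equal-weight special case. The standard error comes from a parametric
#' bootstrap: exposure and outcome effects are redrawn from normal
#' distributions centred at their observed values with the observed standard
#' errors, the median is recomputed for each resample, and the SE is the
#' standard deviation of the resampled estimates.
#'
#' @param h a [harmonized_instruments] object with at least three usable SNPs.
#' @param weighted `TRUE` for the weighted median (default), `FALSE` for the
#'   simple median.
#' @param n_boot number of bootstrap resamples; default 10000. Values below
#'   100 trigger a warning.
#' @param seed integer seed for the bootstrap; mandatory so results are
#'   reproducible.
#' @return An `mr_estimate` (method `"weighted_median"` or
#'   `"simple_median"`).
#' @export
mr_median <- function(h, weighted = TRUE, n_boot = 10000L, seed) {
  stopifnot(inherits(h, "harmonized_instruments"))
  if (missing(seed)) stop("seed is mandatory for the bootstrap SE", call. = FALSE)
  if (n_boot < 100) warning("n_boot < 100: bootstrap SE will be unstable",
                            call. = FALSE)
  use <- h$beta_x != 0
  J <- sum(use)
  if (J < 3) stop("median estimators require at least 3 SNPs with beta_x != 0",
                  call. = FALSE)
  bx <- h$beta_x[use]; sx <- h$se_x[use]
  by <- h$beta_y[use]; sy <- h$se_y[use]
  # canonical orientation (beta_x >= 0): ratios and weights are unchanged,
  # and the bootstrap becomes invariant to per-SNP sign flips of the input
  flip <- bx < 0
  by <- ifelse(flip, -by, by)
  bx <- abs(bx)
  point_of <- function(bx, by) {
    ratio <- by / bx
    w <- if (weighted) (abs(bx) / sy)^2 else rep(1, length(ratio))
    weighted_median_point(ratio, w)
  }
  beta <- point_of(bx, by)
  boot <- withr_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      bxs <- stats::rnorm(J, bx, sx)
      bys <- stats::rnorm(J, by, sy)
      bxs[bxs == 0] <- .Machine$double.eps
      point_of(bxs, bys)
    }, numeric(1))
  })
  if (any(!is.finite(boot))) stop("non-finite bootstrap draws", call. = FALSE)
  mr_estimate(if (weighted) "weighted_median" else "simple_median",
              beta, stats::sd(boot), J)
}

# Evaluates an expression under a local RNG state seeded with `seed`,
# restoring the caller's state afterwards.
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Cochran's Q heterogeneity statistic over instruments
#'
#' `Q = sum(w * (beta_y - beta * beta_x)^2)` with `w = 1/se_y^2`, df = J - 1,
#' p from the upper chi-square tail. Large Q indicates that the per-SNP
#' effects are not proportional, i.e. heterogeneity/pleiotropy.
#'
#' @param h a [harmonized_instruments] object with at least two SNPs.
#' @param beta the causal slope at which residuals are evaluated (typically
#'   the IVW estimate; defaults to it).
#' @return list with elements `q`, `df`, `pvalue`.
#' @export
cochran_q <- function(h, beta = NULL) {
  stopifnot(inherits(h, "harmonized_instruments"))
  J <- n_snps(h)
  if (J < 2) stop("Cochran's Q requires at least 2 SNPs", call. = FALSE)
  if (is.null(beta)) beta <- mr_ivw(h, model = "fixed")$beta
  w <- 1 / h$se_y^2
  q <- sum(w * (h$beta_y - beta * h$beta_x)^2)
  list(q = q, df = J - 1L,
       pvalue = stats::pchisq(q, df = J - 1L, lower.tail = FALSE))
}
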