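#' Fit two-sample Mendelian randomization estimators
#'
#' The package's central fitting function: runs the inverse-variance-weighted
#' estimator (the primary analysis) together with the requested sensitivity
#' estimators (MR-Egger, simple and weighted median) on one harmonized
#' exposure-outcome instrument set, and returns a classed model object with
#' the usual accessors.
#'
#' @param h a [harmonized_instruments] object.
#' @param methods character vector of estimators to run; any of `"ivw"`,
#'   `"egger"`, `"simple_median"`, `"weighted_median"`. Methods whose
#'   minimum SNP count is not met are skipped with a warning.
#' @param model IVW error model, `"random"` (default) or `"fixed"`; see
#'   [mr_ivw()].
#' @param n_boot bootstrap resamples for the median SEs; default 10000.
#' @param seed integer seed for the median bootstrap; required when a median
#'   method is requested.
#' @return An object of class `mr_fit`: a list of `mr_estimate`s plus the
#'   instrument data and metadata. Methods: `print`, `summary`, `coef`,
#'   `confint`, `as.data.frame`.
#' @examples
#' h <- harmonized_instruments(
#'   rsids = paste0("rs", 1:5),
#'   beta_x = c(0.11, 0.09, 0.14, 0.12, 0.10), se_x = rep(0.01, 5),
#'   beta_y = c(0.055, 0.040, 0.075, 0.058, 0.052), se_y = rep(0.01, 5))
#' fit <- mr_fit(h, seed = 1, n_boot = 200)
#' coef(fit)
#' @export
mr_fit <- function(h, methods = c("ivw", "egger", "simple_median", "weighted_median"),
                   model = "random", n_boot = 10000L, seed = NULL) {
  stopifnot(inherits(h, "harmonized_instruments"))
  methods <- match.arg(methods, several.ok = TRUE)
  J <- n_snps(h)
  estimates <- list()
  for (m in methods) {
    need <- if (m == "ivw") 1L else 3L
    if (J < need) {
      warning(sprintf("skipping %s: %d SNP(s) available, %d required", m, J, need),
              call. = FALSE)
      next
    }
    estimates[[m]] <- switch(
      m,
      ivw = mr_ivw(h, model = model),
      egger = mr_egger(h),
      simple_median = {
        if (is.null(seed)) stop("seed required for median bootstrap", call. = FALSE)
        mr_median(h, weighted = FALSE, n_boot = n_boot, seed = seed)
      },
      weighted_median = {
        if (is.null(seed)) stop("seed required for median bootstrap", call. = FALSE)
        mr_median(h, weighted = TRUE, n_boot = n_boot, seed = seed)
      }
    )
  }
  if (!length(estimates)) stop("no estimator could be run", call. = FALSE)
  structure(
    list(estimates = estimates, data = h,
         exposure = h$exposure, outcome = h$outcome, sex = h$sex,
         n_snps = J, model = model, seed = seed),
    class = "mr_fit"
  )
}

#' @export
print.mr_fit <- function(x, ...) {
  cat("Two-sample Mendelian randomization fit\n")
  if (!is.na(x$exposure)) {
    cat(sprintf("  %s -> %s (sex: %s)\n", x$exposure, x$outcome, x$sex))
  }
  cat(sprintf("  instruments: %d SNP(s)\n", x$n_snps))
  for (est in x$estimates) print(est)
  invisible(x)
}

#' @export
summary.mr_fit <- function(object, ...) {
  out <- as.data.frame(object)
  ivw <- object$estimates$ivw
  het <- if (!is.null(ivw) && object$n_snps >= 2) {
    list(q = ivw$q_stat, df = object$n_snps - 1L,
         pvalue = stats::pchisq(ivw$q_stat, object$n_snps - 1L,
                                lower.tail = FALSE))
  }
  structure(list(table = out, heterogeneity = het,
                 exposure = object$exposure, outcome = object$outcome,
                 sex = object$sex, n_snps = object$n_snps),
            class = "summary.mr_fit")
}

#' @export
print.summary.mr_fit <- function(x, ...) {
  cat("Two-sample Mendelian randomization\n")
  if (!is.na(x$exposure)) {
    cat(sprintf("  %s -> %s (sex: %s), %d instrument(s)\n",
                x$exposure, x$outcome, x$sex, x$n_snps))
  }
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], signif, digits = 4)
  print(tab, row.names = FALSE)
  if (!is.null(x$heterogeneity)) {
    cat(sprintf("Heterogeneity: Q = %.2f on %d df, p = %.3g\n",
                x$heterogeneity$q, x$heterogeneity$df, x$heterogeneity$pvalue))
  }
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  vapply(object$estimates, `[[`, numeric(1), "beta")
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  beta <- coef(object)
  se <- vapply(object$estimates, `[[`, numeric(1), "se")
  if (!missing(parm)) { beta <- beta[parm]; se <- se[parm] }
  out <- cbind(beta - z * se, beta + z * se)
  colnames(out) <- sprintf("%g %%", c((1 - level) / 2, 1 - (1 - level) / 2) * 100)
  out
}

#' Flatten a fit into a one-row-per-method estimates table
#'
#' @param x an `mr_fit` object.
#' @param row.names,optional,... ignored (S3 signature).
#' @return data.frame with columns `exposure outcome sex method n_snps beta
#'   se or ci_low ci_high pvalue q_stat egger_intercept egger_intercept_p`.
#' @export
as.data.frame.mr_fit <- function(x, row.names = NULL, optional = FALSE, ...) {
  rows <- lapply(x$estimates, function(e) {
    data.frame(exposure = x$exposure, outcome = x$outcome, sex = x$sex,
               method = e$method, n_snps = e$n_snps, beta = e$beta, se = e$se,
               or = e$or, ci_low = e$ci_low, ci_high = e$ci_high,
               pvalue = e$pvalue, q_stat = e$q_stat,
               egger_intercept = e$egger_intercept,
               egger_intercept_p = e$egger_intercept_p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
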