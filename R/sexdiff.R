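#' Back-convert an odds ratio with 95% CI to log-odds beta and SE
#'
#' Recovers the log-scale estimate from published forest-plot numbers:
#' `beta = ln(OR)`, `se = (ln(upper) - ln(lower)) / (2 * z)` with `z` the
#' exact 0.975 normal quantile. This is the entry point for re-analysing
#' printed per-sex odds ratios when the underlying summary data are not
#' available.
#'
#' @param or_ odds ratio.
#' @param lcl,ucl lower and upper 95% confidence bounds,
#'   `0 < lcl <= or_ <= ucl`.
#' @return named numeric vector `c(beta =, se =)`.
#' @examples
#' ci_to_log(3.81, 1.93, 7.52)
#' @export
ci_to_log <- function(or_, lcl, ucl) {
  stopifnot(is.numeric(or_), is.numeric(lcl), is.numeric(ucl))
  if (any(lcl <= 0) || any(lcl > or_) || any(or_ > ucl)) {
    stop("confidence bounds must satisfy 0 < lcl <= or <= ucl", call. = FALSE)
  }
  c(beta = log(or_), se = (log(ucl) - log(lcl)) / (2 * Z975))
}

#' Between-sex difference test (two-group Cochran's Q)
#'
#' Tests equality of the women's and men's causal estimates with Cochran's Q
#' on two groups: with inverse-variance weights `w_i = 1/se_i^2` and pooled
#' mean `b = sum(w_i b_i)/sum(w_i)`, `Q = sum(w_i (b_i - b)^2)` on 1 degree
#' of freedom. Algebraically Q equals the squared z-statistic
#' `(b_w - b_m)^2 / (se_w^2 + se_m^2)`.
#'
#' @param beta_women,se_women women's log-odds estimate and SE.
#' @param beta_men,se_men men's log-odds estimate and SE.
#' @return An object of class `sex_difference`: list with the inputs,
#'   `q_stat`, `df` (always 1) and `pvalue`.
#' @examples
#' m <- ci_to_log(3.81, 1.93, 7.52)
#' w <- ci_to_log(1.12, 0.63, 1.99)
#' sex_difference(w["beta"], w["se"], m["beta"], m["se"])
#' @export
sex_difference <- function(beta_women, se_women, beta_men, se_men) {
  stopifnot(se_women > 0, se_men > 0)
  w <- c(1 / se_women^2, 1 / se_men^2)
  b <- c(beta_women, beta_men)
  pooled <- sum(w * b) / sum(w)
  q <- sum(w * (b - pooled)^2)
  structure(
    list(beta_women = unname(beta_women), se_women = unname(se_women),
         beta_men = unname(beta_men), se_men = unname(se_men),
         q_stat = unname(q), df = 1L,
         pvalue = stats::pchisq(unname(q), df = 1, lower.tail = FALSE)),
    class = "sex_difference"
  )
}

#' @export
print.sex_difference <- function(x, ...) {
  cat(sprintf("Sex difference (two-group Cochran's Q): Q = %.3f, df = 1, p = %.4g\n",
              x$q_stat, x$pvalue))
  cat(sprintf("  women: beta %.4f (se %.4f); men: beta %.4f (se %.4f)\n",
              x$beta_women, x$se_women, x$beta_men, x$se_men))
  invisible(x)
}

#' Sex-difference tests across an estimates table
#'
#' Pairs the female and male rows of an estimates table (as produced by
#' [as.data.frame.mr_fit()] or [run_analysis()]) for every
#' (exposure, outcome, method) combination and applies [sex_difference()]
#' to each pair. Rows with `p <= 0.05` are flagged.
#'
#' @param estimates data.frame with columns `exposure`, `outcome`, `sex`
#'   (`"female"`/`"male"`), `method`, `beta`, `se`.
#' @param methods which estimators to test; default `"ivw"` only (the
#'   primary analysis).
#' @param alpha flagging threshold; default 0.05.
#' @return data.frame with one row per (exposure, outcome, method):
#'   per-sex betas/SEs, `q_stat`, `df`, `pvalue`, `flagged`.
#' @export
sexdiff_table <- function(estimates, methods = "ivw", alpha = 0.05) {
  need <- c("exposure", "outcome", "sex", "method", "beta", "se")
  stopifnot(all(need %in% names(estimates)))
  est <- estimates[estimates$method %in% methods, , drop = FALSE]
  keys <- unique(est[, c("exposure", "outcome", "method")])
  out <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sub <- est[est$exposure == keys$exposure[i] &
               est$outcome == keys$outcome[i] &
               est$method == keys$method[i], ]
    for (s in c("female", "male")) {
      if (sum(sub$sex == s) != 1L) {
        stop(sprintf("unmatched sex pair for %s -> %s (%s): missing or duplicated '%s'",
                     keys$exposure[i], keys$outcome[i], keys$method[i], s),
             call. = FALSE)
      }
    }
    f <- sub[sub$sex == "female", ]; m <- sub[sub$sex == "male", ]
    sd_ <- sex_difference(f$beta, f$se, m$beta, m$se)
    out[[i]] <- data.frame(
      exposure = keys$exposure[i], outcome = keys$outcome[i],
      method = keys$method[i],
      beta_women = sd_$beta_women, se_women = sd_$se_women,
      beta_men = sd_$beta_men, se_men = sd_$se_men,
      q_stat = sd_$q_stat, df = sd_$df, pvalue = sd_$pvalue,
      flagged = sd_$pvalue <= alpha,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Sex-difference tests from published odds ratios
#'
#' The back-conversion path: takes a table of printed per-sex odds ratios
#' with 95% CIs, converts each row to the log-odds scale via [ci_to_log()],
#' and applies the two-group Cochran's Q test to every female/male pair.
#'
#' @param cis data.frame with columns `exposure`, `outcome`, `sex`, `or`,
#'   `ci_low`, `ci_high`.
#' @param alpha flagging threshold; default 0.05.
#' @return data.frame: the input plus `beta` and `se`, with attribute
#'   `"sexdiff"` holding the paired test table (`q_stat`, `pvalue`,
#'   `flagged` per exposure-outcome).
#' @export
sexdiff_from_cis <- function(cis, alpha = 0.05) {
  need <- c("exposure", "outcome", "sex", "or", "ci_low", "ci_high")
  stopifnot(all(need %in% names(cis)))
  conv <- t(mapply(ci_to_log, cis$or, cis$ci_low, cis$ci_high))
  cis$beta <- conv[, "beta"]
  cis$se <- conv[, "se"]
  cis$method <- "reported"
  structure(cis, sexdiff = sexdiff_table(cis, methods = "reported",
                                         alpha = alpha))
}
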