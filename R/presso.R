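#' MR-PRESSO: pleiotropy residual sum of squares outlier test
#'
#' Simulation-based detection of pleiotropic outlier instruments. For each
#' SNP j the leave-one-out IVW slope `theta_(-j)` (fixed-effect weights
#' `1/se_y^2`) defines the expected outcome effect `theta_(-j) * beta_x_j`;
#' the observed squared residual `RSS_j = (beta_y_j - theta_(-j) beta_x_j)^2`
#' sums to the global statistic. The null distribution is built by
#' parametric simulation: each replicate redraws
#' `beta_x* ~ N(beta_x, se_x)` and `beta_y*_j ~ N(theta_(-j) beta_x_j, se_y_j)`
#' and recomputes the same statistic. The global p-value is the Monte-Carlo
#' tail probability with the `(b+1)/(n_sim+1)` correction, so it is never
#' exactly zero. Per-SNP p-values are Bonferroni-corrected (multiplied by
#' the SNP count, capped at 1); SNPs with corrected p below `alpha` are
#' outliers. When outliers are found, the distortion test compares the IVW
#' estimate before and after their removal,
#' `100 * (beta_raw - beta_corrected) / |beta_corrected|`, against a null
#' built by removing equally many SNPs sampled with replacement from the
#' non-outlier set.
#'
#' @param h a [harmonized_instruments] object with at least four SNPs.
#' @param n_sim number of simulation replicates, at least 1000; default 5000.
#' @param seed integer seed; mandatory for reproducibility.
#' @param alpha outlier significance level applied to the Bonferroni-corrected
#'   per-SNP p-values; default 0.05.
#' @param distortion logical: run the distortion test when outliers are
#'   found; default `TRUE`.
#' @return An object of class `mr_presso`: `rss_obs`, `global_p`, `outliers`
#'   (data.frame `rsid`, `raw_p`, `corrected_p`), `beta_raw`,
#'   `beta_corrected`, `distortion_coef`, `distortion_p`, `n_sim`, `seed`.
#'   Distortion fields are `NA` when no outlier is found.
#' @export
mr_presso <- function(h, n_sim = 5000L, seed, alpha = 0.05, distortion = TRUE) {
  stopifnot(inherits(h, "harmonized_instruments"))
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  J <- n_snps(h)
  if (J < 4) stop("MR-PRESSO requires at least 4 SNPs", call. = FALSE)
  if (n_sim < 1000) stop("n_sim must be at least 1000", call. = FALSE)

  bx <- h$beta_x; sx <- h$se_x; by <- h$beta_y; sy <- h$se_y
  w <- 1 / sy^2

  loo_slopes <- function(bx, by) {
    p <- w * bx * by
    q <- w * bx^2
    (sum(p) - p) / (sum(q) - q)
  }
  theta_loo <- loo_slopes(bx, by)
  rss_j <- (by - theta_loo * bx)^2
  rss_obs <- sum(rss_j)

  withr_seed(seed, {
    mu_y <- theta_loo * bx
    # simulate in one block: n_sim x J matrices, per-replicate leave-one-out
    # slopes obtained by subtracting each column from the row totals
    bxs <- matrix(stats::rnorm(n_sim * J, rep(bx, each = n_sim),
                               rep(sx, each = n_sim)), n_sim, J)
    bys <- matrix(stats::rnorm(n_sim * J, rep(mu_y, each = n_sim),
                               rep(sy, each = n_sim)), n_sim, J)
    wm <- matrix(w, n_sim, J, byrow = TRUE)
    p <- wm * bxs * bys
    q <- wm * bxs^2
    theta_star <- (rowSums(p) - p) / (rowSums(q) - q)
    rss_star <- (bys - theta_star * bxs)^2

    global_p <- (sum(rowSums(rss_star) >= rss_obs) + 1) / (n_sim + 1)
    raw_p <- (colSums(rss_star >= rep(rss_j, each = n_sim)) + 1) / (n_sim + 1)
    corrected_p <- pmin(1, raw_p * J)
    is_out <- corrected_p < alpha
    outliers <- data.frame(rsid = h$rsids[is_out],
                           raw_p = raw_p[is_out],
                           corrected_p = corrected_p[is_out],
                           stringsAsFactors = FALSE)

    beta_raw <- sum(w * bx * by) / sum(w * bx^2)
    beta_corrected <- NA_real_
    distortion_coef <- NA_real_
    distortion_p <- NA_real_
    if (any(is_out)) {
      if (all(is_out)) {
        stop("no reference set: every SNP flagged as an outlier", call. = FALSE)
      }
      keep <- !is_out
      ivw_on <- function(idx) sum(w[idx] * bx[idx] * by[idx]) /
                              sum(w[idx] * bx[idx]^2)
      beta_corrected <- ivw_on(keep)
      if (distortion) {
        distortion_coef <- 100 * (beta_raw - beta_corrected) / abs(beta_corrected)
        ref <- which(keep)
        k <- sum(is_out)
        null_coef <- vapply(seq_len(n_sim), function(i) {
          rem <- unique(ref[sample.int(length(ref), k, replace = TRUE)])
          b <- ivw_on(setdiff(seq_len(J), rem))
          100 * (beta_raw - b) / abs(b)
        }, numeric(1))
        distortion_p <- (sum(abs(null_coef) >= abs(distortion_coef)) + 1) /
                        (n_sim + 1)
      }
    }

    structure(
      list(rss_obs = rss_obs, global_p = global_p, outliers = outliers,
           raw_p_all = stats::setNames(raw_p, h$rsids),
           beta_raw = beta_raw, beta_corrected = beta_corrected,
           distortion_coef = distortion_coef, distortion_p = distortion_p,
           n_sim = as.integer(n_sim), seed = as.integer(seed),
           alpha = alpha, n_snps = J,
           exposure = h$exposure, outcome = h$outcome, sex = h$sex),
      class = "mr_presso"
    )
  })
}

#' @export
print.mr_presso <- function(x, ...) {
  cat(sprintf("MR-PRESSO (%d SNPs, %d simulations)\n", x$n_snps, x$n_sim))
  cat(sprintf("  global RSS = %.4g, p = %.4g\n", x$rss_obs, x$global_p))
  if (nrow(x$outliers)) {
    cat(sprintf("  outliers (%d): %s\n", nrow(x$outliers),
                paste(x$outliers$rsid, collapse = ", ")))
    cat(sprintf("  IVW before/after removal: %.4f / %.4f; distortion %.1f%%, p = %.4g\n",
                x$beta_raw, x$beta_corrected, x$distortion_coef, x$distortion_p))
  } else {
    cat("  no outliers detected\n")
  }
  invisible(x)
}
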