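#' LD reference panel as a SNP-by-SNP correlation matrix
#'
#' @param rsids character vector of variant identifiers.
#' @param r square matrix of pairwise allelic correlations in \[-1, 1\] with
#'   unit diagonal; validated symmetric to 1e-8 and then symmetrized.
#' @return An object of class `ld_panel`.
#' @export
ld_panel <- function(rsids, r) {
  r <- as.matrix(r)
  stopifnot(nrow(r) == length(rsids), ncol(r) == length(rsids))
  if (any(abs(r - t(r)) > 1e-8)) {
    stop("LD matrix not symmetric within 1e-8", call. = FALSE)
  }
  if (any(abs(diag(r) - 1) > 1e-8)) {
    stop("LD matrix diagonal must be 1", call. = FALSE)
  }
  if (any(abs(r) > 1 + 1e-8)) {
    stop("LD correlations must lie in [-1, 1]", call. = FALSE)
  }
  r <- (r + t(r)) / 2
  diag(r) <- 1
  dimnames(r) <- list(rsids, rsids)
  structure(list(rsids = as.character(rsids), r = r), class = "ld_panel")
}

#' Read an LD panel from a delimited text file
#'
#' Expects a square matrix with rsids as the first row (header) and first
#' column.
#'
#' @param path file path.
#' @param sep field separator; default tab.
#' @return An [ld_panel] object.
#' @export
read_ld_panel <- function(path, sep = "\t") {
  m <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1,
                         check.names = FALSE)
  if (!identical(rownames(m), colnames(m))) {
    stop("LD panel row and column rsids disagree", call. = FALSE)
  }
  ld_panel(rownames(m), as.matrix(m))
}

#' Write an LD panel to a delimited text file
#' @param panel an [ld_panel] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ld_panel <- function(panel, path) {
  stopifnot(inherits(panel, "ld_panel"))
  m <- panel$r
  out <- data.frame(rsid = rownames(m), m, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.ld_panel <- function(x, ...) {
  cat(sprintf("LD panel: %d SNPs\n", length(x$rsids)))
  invisible(x)
}

#' Greedy LD clumping of candidate instruments
#'
#' Selects approximately independent index SNPs: candidates passing the
#' p-value threshold are ranked by ascending p-value (ties broken by
#' ascending rsid, making the output invariant to input row order); the best
#' remaining candidate is taken as an index SNP and every remaining candidate
#' with squared correlation above `r2_threshold` against it is pruned; this
#' repeats until no candidates remain. SNPs absent from the panel are dropped
#' with a warning before clumping. Every pair of retained SNPs satisfies
#' r^2 <= `r2_threshold`.
#'
#' @param stats a [summary_stats] object.
#' @param panel an [ld_panel] object covering the candidate SNPs.
#' @param r2_threshold squared-correlation pruning threshold in (0, 1);
#'   default 0.001.
#' @param p_threshold significance threshold applied before clumping;
#'   default 5e-8.
#' @return A [summary_stats] object containing the index SNPs, ordered by
#'   ascending p-value (the selection order), so the output is identical for
#'   any permutation of the input rows.
#' @export
clump <- function(stats, panel, r2_threshold = 0.001, p_threshold = 5e-8) {
  stopifnot(inherits(stats, "summary_stats"), inherits(panel, "ld_panel"),
            r2_threshold > 0, r2_threshold < 1)
  rec <- stats$records
  in_panel <- rec$rsid %in% panel$rsids
  if (any(!in_panel)) {
    warning(sprintf("%d SNP(s) absent from the LD panel dropped before clumping: %s",
                    sum(!in_panel),
                    paste(utils::head(rec$rsid[!in_panel], 5L), collapse = ", ")),
            call. = FALSE)
    rec <- rec[in_panel, , drop = FALSE]
  }
  rec <- rec[rec$pvalue <= p_threshold, , drop = FALSE]
  if (!nrow(rec)) {
    stop(structure(
      class = c("no_instruments_error", "error", "condition"),
      list(message = sprintf("no instruments for trait '%s' (sex %s) at p <= %g",
                             stats$trait, stats$sex, p_threshold),
           call = NULL)))
  }
  ord <- order(rec$pvalue, rec$rsid)
  candidates <- rec$rsid[ord]
  r2 <- panel$r[candidates, candidates, drop = FALSE]^2
  index <- character(0)
  while (length(candidates)) {
    top <- candidates[1L]
    index <- c(index, top)
    keep <- r2[top, candidates] <= r2_threshold
    keep[1L] <- FALSE
    candidates <- candidates[keep]
  }
  stats$records <- rec[match(index, rec$rsid), , drop = FALSE]
  rownames(stats$records) <- NULL
  stats
}

#' Instrument strength: per-SNP and mean F-statistics
#'
#' The per-SNP F-statistic is the squared Wald ratio `(beta / se)^2`; the
#' conventional weak-instrument bar is a mean F above 10 (Staiger-Stock
#' rule of thumb). A warning of class `weak_instruments_warning` is raised
#' when the mean F is 10 or below.
#'
#' @param stats a [summary_stats] object (typically post-filter, post-clump).
#' @return The mean F-statistic, with the per-SNP values in attribute
#'   `per_snp`.
#' @export
mean_f_statistic <- function(stats) {
  stopifnot(inherits(stats, "summary_stats"))
  rec <- stats$records
  if (!nrow(rec)) stop("cannot compute F-statistics on empty summary statistics",
                       call. = FALSE)
  f <- (rec$beta / rec$se)^2
  mf <- mean(f)
  if (mf <= 10) {
    warning(structure(
      class = c("weak_instruments_warning", "warning", "condition"),
      list(message = sprintf("weak instruments: mean F = %.2f <= 10 for '%s' (sex %s)",
                             mf, stats$trait, stats$sex),
           call = NULL)))
  }
  structure(mf, per_snp = stats::setNames(f, rec$rsid))
}

#' Summarize an instrument set
#'
#' @param stats a [summary_stats] object after p-value filtering, MAF
#'   filtering and clumping.
#' @return An object of class `instrument_set` with the retained statistics,
#'   the SNP count and the mean F-statistic.
#' @export
instrument_set <- function(stats) {
  stopifnot(inherits(stats, "summary_stats"))
  mf <- mean_f_statistic(stats)
  structure(list(stats = stats, n_snps = nrow(stats$records),
                 mean_f = as.numeric(mf), f_per_snp = attr(mf, "per_snp")),
            class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("Instrument set: %s (sex %s), %d SNP(s), mean F = %.1f\n",
              x$stats$trait, x$stats$sex, x$n_snps, x$mean_f))
  invisible(x)
}
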