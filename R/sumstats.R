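#' GWAS summary statistics for one trait
#'
#' Container for per-variant association statistics of a single trait in a
#' single (sex-stratified or sex-combined) GWAS. Each record holds a variant's
#' rsid, coordinates, alleles, effect-allele frequency, effect estimate with
#' its standard error, p-value and sample size. Effect sizes for binary traits
#' are on the log-odds-per-allele scale; continuous traits use the unit stated
#' in `unit` (e.g. one standard deviation, 10 mmHg).
#'
#' @param records data.frame with columns `rsid`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pvalue`, `n`.
#' @param trait trait name.
#' @param unit unit of the per-allele effect (e.g. `"SD"`, `"log-odds"`).
#' @param sex one of `"female"`, `"male"`, `"combined"`.
#' @param ancestry ancestry label (metadata only).
#' @return An object of class `summary_stats`.
#' @export
summary_stats <- function(records, trait, unit, sex = c("female", "male", "combined"),
                          ancestry = "European") {
  sex <- match.arg(sex)
  stopifnot(is.character(trait), length(trait) == 1L,
            is.character(unit), length(unit) == 1L)
  records <- validate_records(records)
  structure(
    list(trait = trait, unit = unit, sex = sex, ancestry = ancestry,
         records = records),
    class = "summary_stats"
  )
}

SUMSTATS_COLS <- c("rsid", "chrom", "pos", "effect_allele", "other_allele",
                   "eaf", "beta", "se", "pvalue", "n")

# Validates and canonicalizes a record table. Alleles are upper-cased;
# only single-base A/C/G/T alleles pass (the analysis is SNP-only, so
# indels and multi-allelic codes are rejected at the door). Errors name
# the offending data rows so a malformed consortium file is diagnosable.
validate_records <- function(records) {
  missing_cols <- setdiff(SUMSTATS_COLS, names(records))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  records <- as.data.frame(records)[SUMSTATS_COLS]
  records$rsid <- as.character(records$rsid)
  records$chrom <- as.character(records$chrom)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  for (col in c("pos", "eaf", "beta", "se", "pvalue", "n")) {
    v <- records[[col]]
    if (is.character(v) || is.factor(v)) {
      parsed <- suppressWarnings(as.numeric(as.character(v)))
      bad <- which(is.na(parsed) & !is.na(v))
      if (length(bad)) {
        stop(sprintf("column '%s': unparsable numeric value on data row(s) %s",
                     col, paste(bad, collapse = ", ")), call. = FALSE)
      }
      records[[col]] <- parsed
    }
  }

  fail <- function(test, what) {
    bad <- which(test)
    if (length(bad)) {
      stop(sprintf("%s on data row(s) %s", what, paste(bad, collapse = ", ")),
           call. = FALSE)
    }
  }
  bases <- c("A", "C", "G", "T")
  fail(!(records$effect_allele %in% bases),
       "effect_allele not a single base A/C/G/T (indels/multi-allelic rejected)")
  fail(!(records$other_allele %in% bases),
       "other_allele not a single base A/C/G/T (indels/multi-allelic rejected)")
  fail(records$effect_allele == records$other_allele,
       "effect_allele equal to other_allele")
  fail(!is.finite(records$se) | records$se <= 0, "se not > 0")
  fail(!is.finite(records$eaf) | records$eaf < 0 | records$eaf > 1,
       "eaf outside [0, 1]")
  fail(!is.finite(records$beta), "non-finite beta")
  fail(!is.finite(records$pvalue) | records$pvalue <= 0 | records$pvalue > 1,
       "pvalue outside (0, 1]")
  fail(!is.finite(records$n) | records$n <= 0 | records$n != round(records$n),
       "n not a positive integer")
  fail(!is.finite(records$pos) | records$pos < 1 | records$pos != round(records$pos),
       "pos not a positive 1-based integer")

  records$pos <- as.integer(records$pos)
  records$n <- as.integer(records$n)

  dup <- unique(records$rsid[duplicated(records$rsid)])
  if (length(dup)) {
    stop("duplicate rsid(s): ", paste(dup, collapse = ", "), call. = FALSE)
  }
  rownames(records) <- NULL
  records
}

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a tab- or comma-delimited file with a header row into a
#' [summary_stats] object. Foreign headers (e.g. GWAS-catalog-style
#' `hm_rsid`) are supported through `column_map`. Row order is preserved;
#' any row failing type or range validation aborts the read with a message
#' naming the column and data row.
#'
#' @param path file path.
#' @param trait,unit,sex,ancestry metadata passed to [summary_stats()].
#' @param column_map named character vector mapping canonical field names to
#'   the file's headers, e.g. `c(rsid = "hm_rsid", beta = "hm_beta")`.
#'   Unmapped canonical fields are looked up under their own names.
#' @param sep field separator; `NULL` (default) auto-detects tab vs comma
#'   from the header line.
#' @return A [summary_stats] object.
#' @export
read_sumstats <- function(path, trait, unit, sex = "combined",
                          ancestry = "European", column_map = NULL, sep = NULL) {
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           colClasses = "character", check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "")
  wanted <- stats::setNames(SUMSTATS_COLS, SUMSTATS_COLS)
  if (!is.null(column_map)) {
    unknown <- setdiff(names(column_map), SUMSTATS_COLS)
    if (length(unknown)) {
      stop("column_map names must be canonical fields; unknown: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    wanted[names(column_map)] <- column_map
  }
  missing_cols <- wanted[!(wanted %in% names(raw))]
  if (length(missing_cols)) {
    stop("missing mandatory column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  records <- stats::setNames(raw[, wanted, drop = FALSE], SUMSTATS_COLS)
  summary_stats(records, trait = trait, unit = unit, sex = sex,
                ancestry = ancestry)
}

#' Write summary statistics to a delimited text file
#'
#' Writes the canonical ten-column table (`rsid chrom pos effect_allele
#' other_allele eaf beta se pvalue n`), tab-delimited, with full numeric
#' precision so that a write/read round-trip is exact for finite decimals.
#'
#' @param stats a [summary_stats] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(stats, path) {
  stopifnot(inherits(stats, "summary_stats"))
  rec <- stats$records
  for (col in c("eaf", "beta", "se", "pvalue")) {
    rec[[col]] <- format(rec[[col]], digits = 17, scientific = NA, trim = TRUE)
  }
  utils::write.table(rec, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("GWAS summary statistics: %s [%s], sex = %s, ancestry = %s\n",
              x$trait, x$unit, x$sex, x$ancestry))
  cat(sprintf("  %d variant(s)\n", nrow(x$records)))
  invisible(x)
}

#' Filter summary statistics on association p-value
#'
#' Retains variants with `pvalue <= threshold` (inclusive at the boundary,
#' matching genome-wide significance declared at p <= 5e-8). Order preserved.
#'
#' @param stats a [summary_stats] object.
#' @param threshold retention threshold in (0, 1); default genome-wide
#'   significance, 5e-8.
#' @return A filtered [summary_stats] object.
#' @export
filter_pvalue <- function(stats, threshold = 5e-8) {
  stopifnot(inherits(stats, "summary_stats"),
            is.numeric(threshold), length(threshold) == 1L,
            threshold > 0, threshold < 1)
  stats$records <- stats$records[stats$records$pvalue <= threshold, , drop = FALSE]
  rownames(stats$records) <- NULL
  stats
}

#' Filter summary statistics on minor allele frequency
#'
#' Retains variants with `min(eaf, 1 - eaf) >= min_maf`; i.e. variants whose
#' minor allele frequency is below `min_maf` are excluded.
#'
#' @param stats a [summary_stats] object.
#' @param min_maf minimum minor-allele frequency in (0, 0.5); default 0.05.
#' @return A filtered [summary_stats] object.
#' @export
filter_maf <- function(stats, min_maf = 0.05) {
  stopifnot(inherits(stats, "summary_stats"),
            is.numeric(min_maf), length(min_maf) == 1L,
            min_maf > 0, min_maf < 0.5)
  maf <- pmin(stats$records$eaf, 1 - stats$records$eaf)
  stats$records <- stats$records[maf >= min_maf, , drop = FALSE]
  rownames(stats$records) <- NULL
  stats
}
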