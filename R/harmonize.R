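#' Harmonized exposure-outcome instruments
#'
#' Per-SNP aligned exposure and outcome effects, the unit of data all causal
#' estimators consume. Usually produced by [harmonize()]; the constructor is
#' exported so simulated effects can be assembled directly.
#'
#' @param rsids character vector of variant identifiers.
#' @param beta_x,se_x SNP-exposure effects and standard errors.
#' @param beta_y,se_y SNP-outcome effects and standard errors, aligned to the
#'   exposure effect allele.
#' @param dropped data.frame with columns `rsid`, `reason` recording variants
#'   excluded during harmonization.
#' @param exposure,outcome,sex optional metadata labels echoed into results.
#' @return An object of class `harmonized_instruments`.
#' @export
harmonized_instruments <- function(rsids, beta_x, se_x, beta_y, se_y,
                                   dropped = data.frame(rsid = character(),
                                                        reason = character()),
                                   exposure = NA_character_,
                                   outcome = NA_character_,
                                   sex = NA_character_) {
  j <- length(rsids)
  stopifnot(length(beta_x) == j, length(se_x) == j,
            length(beta_y) == j, length(se_y) == j,
            all(se_x > 0), all(se_y > 0),
            all(c("rsid", "reason") %in% names(dropped)))
  structure(
    list(rsids = as.character(rsids),
         beta_x = as.numeric(beta_x), se_x = as.numeric(se_x),
         beta_y = as.numeric(beta_y), se_y = as.numeric(se_y),
         dropped = dropped,
         exposure = exposure, outcome = outcome, sex = sex),
    class = "harmonized_instruments"
  )
}

#' @export
print.harmonized_instruments <- function(x, ...) {
  cat(sprintf("Harmonized instruments: %d SNP(s) retained, %d dropped\n",
              length(x$rsids), nrow(x$dropped)))
  if (!is.na(x$exposure)) {
    cat(sprintf("  %s -> %s (%s)\n", x$exposure, x$outcome, x$sex))
  }
  if (nrow(x$dropped)) {
    tab <- table(x$dropped$reason)
    for (r in names(tab)) cat(sprintf("  dropped [%s]: %d\n", r, tab[[r]]))
  }
  invisible(x)
}

#' Number of retained instruments
#' @param h a `harmonized_instruments` object.
#' @return integer count of retained SNPs.
#' @export
n_snps <- function(h) {
  stopifnot(inherits(h, "harmonized_instruments"))
  length(h$rsids)
}

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(a1, a2) {
  (a1 == "A" & a2 == "T") | (a1 == "T" & a2 == "A") |
  (a1 == "C" & a2 == "G") | (a1 == "G" & a2 == "C")
}

#' Harmonize outcome associations to the exposure effect alleles
#'
#' Aligns SNP-outcome effects to the SNP-exposure effect allele for every
#' variant shared between the two studies. For non-palindromic variants the
#' allele labels identify the orientation: matching alleles are kept as-is,
#' swapped alleles (effect and other interchanged) negate the outcome beta
#' and reflect its frequency, and strand-complemented labels (A<->T, C<->G)
#' are complemented first and then resolved the same way. Palindromic (A/T,
#' G/C) variants carry no strand information in their labels, so they are
#' oriented by allele frequency: if the minor-allele frequency in either
#' study exceeds `0.5 - palindrome_eaf_window` the variant is dropped as an
#' ambiguous palindrome, otherwise the outcome is flipped whenever the two
#' studies' effect-allele frequencies fall on opposite sides of 0.5.
#' Irreconcilable allele sets are dropped. Exposure effects are never
#' altered. Every shared variant lands either in the retained set or in the
#' dropped table with its reason.
#'
#' @param exposure,outcome [summary_stats] objects.
#' @param palindrome_eaf_window half-width of the frequency ambiguity zone
#'   around 0.5 for palindromic variants; default 0.08 (drop if MAF > 0.42).
#' @return A [harmonized_instruments] object.
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_window = 0.08) {
  stopifnot(inherits(exposure, "summary_stats"),
            inherits(outcome, "summary_stats"),
            palindrome_eaf_window >= 0, palindrome_eaf_window < 0.5)
  shared <- intersect(exposure$records$rsid, outcome$records$rsid)
  if (!length(shared)) {
    stop("no shared rsids between exposure and outcome summary statistics",
         call. = FALSE)
  }
  ex <- exposure$records[match(shared, exposure$records$rsid), ]
  ou <- outcome$records[match(shared, outcome$records$rsid), ]

  keep <- logical(length(shared))
  reason <- character(length(shared))
  beta_y <- ou$beta
  eaf_y <- ou$eaf

  pal_x <- is_palindromic(ex$effect_allele, ex$other_allele)
  for (i in seq_along(shared)) {
    ea_x <- ex$effect_allele[i]; oa_x <- ex$other_allele[i]
    ea_y <- ou$effect_allele[i]; oa_y <- ou$other_allele[i]
    if (pal_x[i]) {
      same_set <- (ea_y == ea_x && oa_y == oa_x) || (ea_y == oa_x && oa_y == ea_x)
      if (!same_set) { reason[i] <- "allele mismatch"; next }
      maf_x <- min(ex$eaf[i], 1 - ex$eaf[i])
      maf_y <- min(ou$eaf[i], 1 - ou$eaf[i])
      if (max(maf_x, maf_y) > 0.5 - palindrome_eaf_window) {
        reason[i] <- "ambiguous palindrome"; next
      }
      if (sign(ex$eaf[i] - 0.5) != sign(ou$eaf[i] - 0.5)) {
        beta_y[i] <- -beta_y[i]
        eaf_y[i] <- 1 - eaf_y[i]
      }
      keep[i] <- TRUE
    } else {
      cea <- COMPLEMENT[[ea_y]]; coa <- COMPLEMENT[[oa_y]]
      if (ea_y == ea_x && oa_y == oa_x) {
        keep[i] <- TRUE
      } else if (ea_y == oa_x && oa_y == ea_x) {
        beta_y[i] <- -beta_y[i]; eaf_y[i] <- 1 - eaf_y[i]; keep[i] <- TRUE
      } else if (cea == ea_x && coa == oa_x) {
        keep[i] <- TRUE
      } else if (cea == oa_x && coa == ea_x) {
        beta_y[i] <- -beta_y[i]; eaf_y[i] <- 1 - eaf_y[i]; keep[i] <- TRUE
      } else {
        reason[i] <- "allele mismatch"
      }
    }
  }

  h <- harmonized_instruments(
    rsids = shared[keep],
    beta_x = ex$beta[keep], se_x = ex$se[keep],
    beta_y = beta_y[keep], se_y = ou$se[keep],
    dropped = data.frame(rsid = shared[!keep], reason = reason[!keep],
                         stringsAsFactors = FALSE),
    exposure = exposure$trait, outcome = outcome$trait, sex = outcome$sex
  )
  h$eaf_x <- ex$eaf[keep]
  h$eaf_y <- eaf_y[keep]
  h
}
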