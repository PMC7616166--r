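#' Define a sex-stratified MR analysis plan
#'
#' Declares the full study design: which exposures are analysed against
#' which outcomes, per sex, with which thresholds. Exposure instruments may
#' be sex-specific or sex-combined; a sex-combined instrument source is
#' applied identically to both sexes' outcome data (the design used for
#' traits where no sex-specific GWAS exists). Every referenced file is read
#' and validated here, before any analysis runs, so a malformed input fails
#' fast with no partial output.
#'
#' @param exposures list of exposure descriptors; each a list with `trait`,
#'   `unit`, and one or more of `female`, `male`, `combined`, each either a
#'   [summary_stats] object or a file path readable by [read_sumstats()].
#' @param outcomes list of outcome descriptors; each a list with `trait` and
#'   per-sex entries `female` and `male` ([summary_stats] or path).
#' @param panel an [ld_panel], a file path for [read_ld_panel()], or `NULL`
#'   to skip LD clumping (instruments assumed pre-pruned).
#' @param p_threshold,min_maf,r2_threshold instrument selection thresholds;
#'   defaults: genome-wide significance 5e-8, MAF 5%, clumping r^2 0.001.
#' @param palindrome_eaf_window passed to [harmonize()].
#' @param methods estimators to run per analysis unit; see [mr_fit()].
#' @param n_boot median bootstrap resamples.
#' @param presso_n_sim MR-PRESSO replicates (0 disables MR-PRESSO).
#' @param presso_alpha MR-PRESSO outlier significance level.
#' @param seed master seed; every stochastic step derives its own stream
#'   from it, so plan + seed fully determine all outputs.
#' @return An object of class `analysis_plan`.
#' @export
analysis_plan <- function(exposures, outcomes, panel = NULL,
                          p_threshold = 5e-8, min_maf = 0.05,
                          r2_threshold = 0.001,
                          palindrome_eaf_window = 0.08,
                          methods = c("ivw", "egger", "simple_median",
                                      "weighted_median"),
                          n_boot = 2000L,
                          presso_n_sim = 5000L, presso_alpha = 0.05,
                          seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  load_stats <- function(x, trait, unit, sex) {
    if (inherits(x, "summary_stats")) return(x)
    if (is.character(x) && length(x) == 1L) {
      if (!file.exists(x)) stop("file not found: ", x, call. = FALSE)
      return(read_sumstats(x, trait = trait, unit = unit, sex = sex))
    }
    stop("expected a summary_stats object or a file path", call. = FALSE)
  }
  exposures <- lapply(exposures, function(e) {
    stopifnot(!is.null(e$trait))
    if (is.null(e$unit)) e$unit <- "SD"
    for (s in c("female", "male", "combined")) {
      if (!is.null(e[[s]])) {
        e[[s]] <- load_stats(e[[s]], e$trait, e$unit, s)
        e[[s]]$sex <- s  # the plan slot, not the file, defines the role
      }
    }
    if (is.null(e$female) && is.null(e$male) && is.null(e$combined)) {
      stop("exposure '", e$trait, "' has no instrument source", call. = FALSE)
    }
    e
  })
  outcomes <- lapply(outcomes, function(o) {
    stopifnot(!is.null(o$trait), !is.null(o$female), !is.null(o$male))
    o$female <- load_stats(o$female, o$trait, "log-odds", "female")
    o$female$sex <- "female"
    o$male <- load_stats(o$male, o$trait, "log-odds", "male")
    o$male$sex <- "male"
    o
  })
  if (is.character(panel)) panel <- read_ld_panel(panel)
  if (!is.null(panel)) stopifnot(inherits(panel, "ld_panel"))
  structure(
    list(exposures = exposures, outcomes = outcomes, panel = panel,
         p_threshold = p_threshold, min_maf = min_maf,
         r2_threshold = r2_threshold,
         palindrome_eaf_window = palindrome_eaf_window,
         methods = methods, n_boot = as.integer(n_boot),
         presso_n_sim = as.integer(presso_n_sim),
         presso_alpha = presso_alpha, seed = as.integer(seed)),
    class = "analysis_plan"
  )
}

# Small stable content hash (FNV-1a over the deparsed configuration) used
# only for provenance stamping of outputs.
plan_hash <- function(plan) {
  cfg <- plan[c("p_threshold", "min_maf", "r2_threshold",
                "palindrome_eaf_window", "methods", "n_boot",
                "presso_n_sim", "presso_alpha", "seed")]
  bytes <- utf8ToInt(paste(deparse(cfg), collapse = ""))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", h)
}

#' Run the full sex-stratified MR study
#'
#' For every exposure x outcome x sex analysis unit: p-value filter, MAF
#' filter, LD clumping, instrument-strength summary, harmonization against
#' the sex-specific outcome, causal estimation with every configured method,
#' Cochran's Q heterogeneity, and MR-PRESSO. Units with zero instruments are
#' recorded as failed and the run continues. Finally the female/male IVW
#' estimates are paired into the between-sex Cochran's Q table.
#'
#' @param plan an [analysis_plan].
#' @param progress print per-unit progress messages; default `FALSE`.
#' @return An object of class `study_results`: data.frames `estimates`,
#'   `sexdiffs`, `instrument_summary`, `presso`, `failed`, plus `provenance`
#'   (config hash, seed, timestamp).
#' @export
run_analysis <- function(plan, progress = FALSE) {
  stopifnot(inherits(plan, "analysis_plan"))
  estimates <- list(); instr <- list(); presso <- list(); failed <- list()
  unit <- 0L
  for (ex in plan$exposures) {
    for (ou in plan$outcomes) {
      for (sex in c("female", "male")) {
        unit <- unit + 1L
        unit_seed <- (plan$seed + 7919L * unit) %% .Machine$integer.max
        src <- if (!is.null(ex[[sex]])) ex[[sex]] else ex$combined
        if (is.null(src)) {
          failed[[length(failed) + 1L]] <- data.frame(
            exposure = ex$trait, outcome = ou$trait, sex = sex,
            reason = sprintf("no %s or combined instrument source", sex))
          next
        }
        if (progress) {
          message(sprintf("[%s -> %s, %s]", ex$trait, ou$trait, sex))
        }
        res <- tryCatch({
          sel <- filter_maf(filter_pvalue(src, plan$p_threshold), plan$min_maf)
          if (!is.null(plan$panel)) {
            sel <- clump(sel, plan$panel, plan$r2_threshold, plan$p_threshold)
          }
          if (!nrow(sel$records)) {
            stop(structure(class = c("no_instruments_error", "error", "condition"),
                           list(message = sprintf(
                             "no instruments for trait '%s' (sex %s)",
                             src$trait, src$sex), call = NULL)))
          }
          iset <- withCallingHandlers(
            instrument_set(sel),
            weak_instruments_warning = function(w) {
              message("warning: ", conditionMessage(w))
              invokeRestart("muffleWarning")
            })
          h <- harmonize(sel, ou[[sex]], plan$palindrome_eaf_window)
          fit <- mr_fit(h, methods = plan$methods, n_boot = plan$n_boot,
                        seed = unit_seed)
          est <- as.data.frame(fit)
          est$exposure <- ex$trait; est$outcome <- ou$trait; est$sex <- sex
          pr <- NULL
          if (plan$presso_n_sim >= 1000 && n_snps(h) >= 4) {
            p <- mr_presso(h, n_sim = plan$presso_n_sim, seed = unit_seed,
                           alpha = plan$presso_alpha)
            pr <- data.frame(
              exposure = ex$trait, outcome = ou$trait, sex = sex,
              n_snps = p$n_snps, rss_obs = p$rss_obs, global_p = p$global_p,
              n_outliers = nrow(p$outliers),
              outlier_rsids = paste(p$outliers$rsid, collapse = ";"),
              beta_raw = p$beta_raw, beta_corrected = p$beta_corrected,
              distortion_coef = p$distortion_coef,
              distortion_p = p$distortion_p, stringsAsFactors = FALSE)
          }
          list(est = est,
               instr = data.frame(exposure = ex$trait, outcome = ou$trait,
                                  sex = sex, source_sex = src$sex,
                                  n_snps = iset$n_snps, mean_f = iset$mean_f,
                                  n_dropped = nrow(h$dropped),
                                  stringsAsFactors = FALSE),
               presso = pr)
        }, no_instruments_error = function(e) {
          structure(list(reason = conditionMessage(e)), class = "unit_failure")
        })
        if (inherits(res, "unit_failure")) {
          failed[[length(failed) + 1L]] <- data.frame(
            exposure = ex$trait, outcome = ou$trait, sex = sex,
            reason = res$reason, stringsAsFactors = FALSE)
        } else {
          estimates[[length(estimates) + 1L]] <- res$est
          instr[[length(instr) + 1L]] <- res$instr
          if (!is.null(res$presso)) presso[[length(presso) + 1L]] <- res$presso
        }
      }
    }
  }
  bind <- function(x) if (length(x)) do.call(rbind, x) else NULL
  estimates <- bind(estimates)
  sexdiffs <- NULL
  if (!is.null(estimates) && "ivw" %in% estimates$method) {
    complete <- stats::aggregate(sex ~ exposure + outcome,
                                 data = estimates[estimates$method == "ivw", ],
                                 FUN = function(s) length(unique(s)))
    ok <- complete[complete$sex == 2L, c("exposure", "outcome")]
    if (nrow(ok)) {
      paired <- merge(estimates[estimates$method == "ivw", ], ok)
      sexdiffs <- sexdiff_table(paired, methods = "ivw")
    }
  }
  structure(
    list(estimates = estimates, sexdiffs = sexdiffs,
         instrument_summary = bind(instr), presso = bind(presso),
         failed = bind(failed),
         provenance = list(config_hash = plan_hash(plan), seed = plan$seed,
                           timestamp = format(Sys.time(), tz = "UTC"),
                           n_tests = if (is.null(sexdiffs)) 0L else nrow(sexdiffs))),
    class = "study_results"
  )
}

#' @export
print.study_results <- function(x, ...) {
  cat("Sex-stratified MR study results\n")
  cat(sprintf("  analysis units: %d completed, %d failed\n",
              if (is.null(x$instrument_summary)) 0L else nrow(x$instrument_summary),
              if (is.null(x$failed)) 0L else nrow(x$failed)))
  if (!is.null(x$sexdiffs)) {
    cat(sprintf("  sex-difference tests: %d (no multiplicity correction applied)\n",
                nrow(x$sexdiffs)))
    flagged <- x$sexdiffs[x$sexdiffs$flagged, ]
    if (nrow(flagged)) {
      for (i in seq_len(nrow(flagged))) {
        cat(sprintf("    %s -> %s: p = %.3g\n", flagged$exposure[i],
                    flagged$outcome[i], flagged$pvalue[i]))
      }
    }
  }
  cat(sprintf("  provenance: config %s, seed %d\n",
              x$provenance$config_hash, x$provenance$seed))
  invisible(x)
}

# round half away from zero at d decimals (matches how the source
# literature prints ORs and p-values)
round_half_away <- function(x, d) sign(x) * floor(abs(x) * 10^d + 0.5) / 10^d

format_or <- function(x) sprintf("%.2f", round_half_away(x, 2))

format_p <- function(x) {
  ifelse(x < 0.001, "<0.001", sprintf("%.3f", round_half_away(x, 3)))
}

#' Write the forest-plot-ready results table
#'
#' One row per (exposure, outcome, sex) with the IVW odds ratio, 95% CI,
#' p-value and SNP count, plus the paired between-sex difference p — the
#' exact numeric content of a forest-plot row. ORs and CIs are rendered to
#' 2 decimals and p-values to 3 decimals (round half away from zero;
#' p below 0.001 as `<0.001`).
#'
#' @param results a `study_results` object.
#' @param path output file path (tab-delimited).
#' @return The formatted data.frame, invisibly.
#' @export
write_forest_table <- function(results, path) {
  stopifnot(inherits(results, "study_results"))
  est <- results$estimates[results$estimates$method == "ivw", ]
  if (is.null(est) || !nrow(est)) stop("no IVW estimates to write", call. = FALSE)
  sd_ <- results$sexdiffs
  rows <- lapply(seq_len(nrow(est)), function(i) {
    e <- est[i, ]
    sdp <- ""
    if (!is.null(sd_)) {
      hit <- sd_[sd_$exposure == e$exposure & sd_$outcome == e$outcome, ]
      if (nrow(hit) == 1L) sdp <- format_p(hit$pvalue)
    }
    data.frame(exposure = e$exposure, outcome = e$outcome, sex = e$sex,
               n_snps = e$n_snps, or = format_or(e$or),
               ci_low = format_or(e$ci_low), ci_high = format_or(e$ci_high),
               pvalue = format_p(e$pvalue), sexdiff_p = sdp,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
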