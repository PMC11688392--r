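#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment across a family of tests (here:
#' all exposures analyzed against one outcome). Thin wrapper over
#' [stats::p.adjust()] with an explicit family size.
#'
#' @param pvals Raw p-values in (0, 1].
#' @param m Family size; defaults to `length(pvals)`. Larger values reproduce
#'   the adjustment of a wider panel in which the remaining tests were not
#'   computed here.
#' @return Adjusted p-values, mapped back to the input order.
#' @export
bh_fdr <- function(pvals, m = length(pvals)) {
  if (length(pvals) == 0L) return(numeric(0))
  stopifnot(all(pvals > 0 & pvals <= 1), m >= length(pvals))
  stats::p.adjust(pvals, method = "BH", n = m)
}

#' Classify a causal estimate as protective, risk, or null
#'
#' Significant effects (adjusted, or raw in nominal mode, p-value below
#' `alpha`) with OR < 1 are protective and with OR > 1 are risk; everything
#' else is null. A significant OR exactly equal to 1 is degenerate and
#' raises an error.
#'
#' @param or_ Odds ratio.
#' @param p P-value to gate on (FDR-adjusted for the primary analysis, raw
#'   nominal for subtype analyses reported without multiplicity control).
#' @param alpha Significance level (default 0.05).
#' @return `"protective"`, `"risk"`, or `"null"`.
#' @export
classify <- function(or_, p, alpha = 0.05) {
  if (is.na(p) || p >= alpha) return("null")
  if (or_ < 1) return("protective")
  if (or_ > 1) return("risk")
  stop("classify: significant effect with OR exactly 1 is degenerate",
       call. = FALSE)
}

#' Assemble the run configuration for a panel analysis
#'
#' @param exposures Named list of exposure inputs: each element a canonical
#'   summary-statistics data frame or a file path.
#' @param outcomes Named list of outcome inputs, same conventions.
#' @param pval_threshold,clump_r2,clump_kb,f_min Instrument-selection
#'   thresholds (defaults: 1e-8, 0.001, 10,000 kb, 10).
#' @param fdr_alpha FDR threshold for the significance gate (default 0.05).
#' @param ci_level Confidence level for odds-ratio intervals.
#' @param palindromic_eaf_window Harmonization ambiguity window.
#' @param n_boot Bootstrap replicates for median/mode standard errors.
#' @param presso_n_sim MR-PRESSO simulations; set `run_presso = FALSE` to
#'   skip the (expensive) PRESSO stage.
#' @param run_presso Logical.
#' @param fdr_gate If `FALSE`, classification uses nominal raw p-values
#'   instead of FDR-adjusted ones (the convention used for subtype analyses
#'   whose findings do not survive multiplicity correction).
#' @param pairwise_r2 Optional LD table (see [clump()]) or a path to a
#'   3-column TSV (`snp_a`, `snp_b`, `r2`).
#' @param class_labels Optional two-column data frame (`exposure`, `class`)
#'   of user-supplied biomarker class labels.
#' @param seed Base RNG seed; per-pair seeds are derived deterministically.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(exposures, outcomes,
                       pval_threshold = 1e-8, clump_r2 = 0.001,
                       clump_kb = 10000, f_min = 10, fdr_alpha = 0.05,
                       ci_level = 0.95, palindromic_eaf_window = 0.08,
                       n_boot = 1000, presso_n_sim = 1000,
                       run_presso = TRUE, fdr_gate = TRUE,
                       pairwise_r2 = NULL, class_labels = NULL, seed = 1L) {
  stopifnot(length(exposures) >= 1, length(outcomes) >= 1,
            fdr_alpha > 0, fdr_alpha < 1)
  if (is.null(names(exposures)) || any(names(exposures) == "")) {
    stop("run_config: exposures must be a named list", call. = FALSE)
  }
  if (is.null(names(outcomes)) || any(names(outcomes) == "")) {
    stop("run_config: outcomes must be a named list", call. = FALSE)
  }
  if (is.character(pairwise_r2) && length(pairwise_r2) == 1L) {
    pairwise_r2 <- utils::read.delim(pairwise_r2, stringsAsFactors = FALSE)
  }
  structure(list(
    exposures = exposures, outcomes = outcomes,
    pval_threshold = pval_threshold, clump_r2 = clump_r2,
    clump_kb = clump_kb, f_min = f_min, fdr_alpha = fdr_alpha,
    ci_level = ci_level, palindromic_eaf_window = palindromic_eaf_window,
    n_boot = n_boot, presso_n_sim = presso_n_sim,
    run_presso = isTRUE(run_presso), fdr_gate = isTRUE(fdr_gate),
    pairwise_r2 = pairwise_r2, class_labels = class_labels,
    seed = as.integer(seed)
  ), class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Flat keys mirror the [run_config()] arguments; `exposures` and `outcomes`
#' are maps from trait name to file path.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(run_config, cfg)
}

as_records <- function(x, what) {
  if (is.character(x) && length(x) == 1L) return(read_summary_table(x))
  if (is.data.frame(x)) return(x)
  stop("cannot interpret ", what, " input", call. = FALSE)
}

#' Run the full MR analysis over a biomarker panel
#'
#' For every exposure-outcome pair: select instruments (significance filter,
#' LD clumping, F-statistic exclusion), harmonize to a common effect-allele
#' orientation, estimate the causal effect with IVW (fixed or random effects
#' chosen by the Cochran's Q rule), MR-Egger, weighted median and weighted
#' mode, and run the diagnostics suite (Q, Egger intercept, MR-PRESSO,
#' Steiger, leave-one-out, funnel data). IVW p-values are then
#' Benjamini-Hochberg adjusted per outcome across the exposure panel and
#' every estimate is classified as protective/risk/null.
#'
#' Pairs with fewer than two surviving instruments are skipped with a logged
#' reason rather than failing the run. All randomness (bootstrap and PRESSO
#' resampling) is seeded deterministically from the config seed, so a rerun
#' with the same config is byte-identical.
#'
#' @param config A `run_config`.
#' @return A list with `results` (one row per exposure, outcome and method:
#'   `Exposure`, `Outcome`, `Method`, `nsnp`, `b`, `se`, `Or`, `pval`,
#'   `p_fdr`, `classification`, plus `ci_low`/`ci_high`/`model`),
#'   `diagnostics` (per-pair list), and `log` (character vector of selection
#'   and skip events).
#' @export
run_mr <- function(config) {
  stopifnot(inherits(config, "run_config"))
  results <- list()
  diagnostics <- list()
  log <- character(0)
  note <- function(...) log <<- c(log, sprintf(...))

  outcome_tabs <- lapply(config$outcomes, as_records, what = "outcome")
  exposure_tabs <- lapply(config$exposures, as_records, what = "exposure")

  pair_idx <- 0L
  for (out_name in names(outcome_tabs)) {
    out_tab <- outcome_tabs[[out_name]]
    for (exp_name in names(exposure_tabs)) {
      pair_idx <- pair_idx + 1L
      pair_seed <- (config$seed + 7919L * pair_idx) %% .Machine$integer.max
      exp_tab <- exposure_tabs[[exp_name]]

      iv <- select_instruments(exp_tab, config$pairwise_r2,
                               pval_threshold = config$pval_threshold,
                               window_kb = config$clump_kb,
                               r2_max = config$clump_r2,
                               f_min = config$f_min)
      audit <- attr(iv, "audit")
      note("%s ~ %s: %d instruments (excluded: %d pval, %d clump, %d weak)",
           exp_name, out_name, nrow(iv), audit[["n_failed_pval"]],
           audit[["n_clumped_out"]], audit[["n_weak"]])

      h <- harmonize(iv, out_tab, config$palindromic_eaf_window)
      note("%s ~ %s: harmonized %d SNPs (%d flipped, %d palindromic dropped, %d mismatched)",
           exp_name, out_name, nrow(h), attr(h, "n_flipped"),
           attr(h, "n_dropped_palindromic"), attr(h, "n_dropped_mismatch"))
      k <- nrow(h)
      if (k < 2) {
        note("%s ~ %s: skipped (fewer than 2 surviving instruments)",
             exp_name, out_name)
        next
      }

      q <- cochran_q(h)
      model <- heterogeneity_policy(q)
      ests <- list(mr_ivw(h, model = model, level = config$ci_level))
      diag <- list(q = q$q, q_df = q$df, q_pval = q$pval, model = model)

      if (k >= 3) {
        eg <- mr_egger(h, level = config$ci_level)
        it <- egger_intercept_test(eg)
        ests <- c(ests, list(
          eg$slope,
          mr_weighted_median(h, n_boot = config$n_boot, seed = pair_seed,
                             level = config$ci_level),
          mr_weighted_mode(h, n_boot = config$n_boot, seed = pair_seed + 1L,
                           level = config$ci_level)))
        diag$egger_intercept <- eg$intercept
        diag$egger_intercept_pval <- eg$intercept_pval
        diag$pleiotropy_present <- it$pleiotropy_present
        loo <- leave_one_out(h, level = config$ci_level)
        diag$loo_stable <- !attr(loo, "unstable")
        diag$leave_one_out <- loo
      }
      if (config$run_presso && k >= 4) {
        pr <- mr_presso(h, n_sim = config$presso_n_sim, seed = pair_seed + 2L)
        diag$presso_global_pval <- pr$global_pval
        diag$presso_outliers <- pr$outliers
        diag$presso_distortion_pval <- pr$distortion_pval
        if (!is.null(pr$corrected)) {
          diag$presso_corrected_b <- pr$corrected$b
          diag$presso_corrected_se <- pr$corrected$se
        }
      }
      if (!all(is.na(h$eaf_exposure))) {
        st <- steiger(h, n_exposure = max(iv$n),
                      n_outcome = max(out_tab$n))
        diag$steiger_direction <- st$direction_correct
        diag$steiger_pval <- st$pval
      }
      diag$funnel <- funnel_data(h)

      diagnostics[[paste(exp_name, out_name, sep = " ~ ")]] <- diag
      for (est in ests) {
        results[[length(results) + 1L]] <- data.frame(
          Exposure = exp_name, Outcome = out_name,
          Method = method_label(est$method), nsnp = est$nsnp,
          b = est$b, se = est$se, Or = est$or_, pval = est$pval,
          p_fdr = NA_real_, ci_low = est$ci_low, ci_high = est$ci_high,
          model = ifelse(is.na(est$model), "", est$model),
          stringsAsFactors = FALSE)
      }
    }
  }

  res <- if (length(results)) do.call(rbind, results) else
    data.frame(Exposure = character(0), Outcome = character(0),
               Method = character(0), nsnp = integer(0), b = numeric(0),
               se = numeric(0), Or = numeric(0), pval = numeric(0),
               p_fdr = numeric(0), ci_low = numeric(0), ci_high = numeric(0),
               model = character(0), stringsAsFactors = FALSE)

  # FDR family: IVW p-values across the exposure panel, per outcome.
  for (out_name in unique(res$Outcome)) {
    sel <- res$Outcome == out_name & res$Method == "IVW"
    res$p_fdr[sel] <- bh_fdr(res$pval[sel])
  }
  gate <- if (config$fdr_gate) ifelse(is.na(res$p_fdr), res$pval, res$p_fdr)
          else res$pval
  res$classification <- vapply(seq_len(nrow(res)), function(i) {
    classify(res$Or[i], gate[i], config$fdr_alpha)
  }, character(1))

  if (!is.null(config$class_labels)) {
    res$class <- config$class_labels$class[
      match(res$Exposure, config$class_labels$exposure)]
  }

  list(results = res, diagnostics = diagnostics, log = log)
}

method_label <- function(m) {
  switch(m, ivw = "IVW", wald = "Wald ratio", egger = "MR Egger",
         weighted_median = "Weighted median", weighted_mode = "Weighted mode",
         m)
}

.report_cols <- c("Exposure", "Outcome", "Method", "nsnp", "b", "se", "Or",
                  "pval", "p_fdr")

#' Write per-outcome report tables and diagnostics
#'
#' Writes one TSV per outcome with the nine canonical report columns
#' (`Exposure`, `Outcome`, `Method`, `nsnp`, `b`, `se`, `Or`, `pval`,
#' `p_fdr`), rows sorted by ascending `b`; a JSON diagnostics sidecar; and a
#' JSON run-metadata file with the configuration echo and package version.
#'
#' @param run A result from [run_mr()].
#' @param dir Output directory (created if needed).
#' @param config Optional `run_config` to echo into the metadata file.
#' @return Character vector of the files written, invisibly.
#' @export
write_report <- function(run, dir, config = NULL) {
  stopifnot(nrow(run$results) > 0)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  for (out_name in unique(run$results$Outcome)) {
    sub <- run$results[run$results$Outcome == out_name, , drop = FALSE]
    sub <- sub[order(sub$b), .report_cols, drop = FALSE]
    f <- file.path(dir, paste0("results_", sanitize_name(out_name), ".tsv"))
    utils::write.table(sub, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  dfile <- file.path(dir, "diagnostics.json")
  diag_slim <- lapply(run$diagnostics, function(d) {
    d$leave_one_out <- NULL
    d$funnel <- NULL
    d
  })
  jsonlite::write_json(diag_slim, dfile, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, dfile)
  mfile <- file.path(dir, "run_meta.json")
  meta <- list(
    package = "metabomr",
    version = as.character(utils::packageVersion("metabomr")),
    log = run$log
  )
  if (!is.null(config)) {
    cfg_echo <- unclass(config)
    cfg_echo$exposures <- names(config$exposures)
    cfg_echo$outcomes <- names(config$outcomes)
    cfg_echo$pairwise_r2 <- NULL
    cfg_echo$class_labels <- NULL
    meta$config <- cfg_echo
  }
  jsonlite::write_json(meta, mfile, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  files <- c(files, mfile)
  invisible(files)
}

sanitize_name <- function(x) gsub("[^A-Za-z0-9._-]+", "_", x)
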