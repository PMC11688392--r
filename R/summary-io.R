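#' @importFrom utils read.delim write.table head
NULL

.canonical_cols <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
                     "eaf", "beta", "se", "pval", "n")

.complement <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic_pair <- function(a1, a2) {
  !is.na(a1) & !is.na(a2) & .complement[a1] == a2
}

#' Read a GWAS summary-statistics table
#'
#' Reads a tab-separated summary-statistics file into the canonical layout
#' (`snp_id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `eaf`, `beta`,
#' `se`, `pval`, `n`). Dialects with different column names are handled via
#' `column_map`. Rows violating the basic record invariants (se <= 0, eaf
#' outside [0, 1], p-value outside (0, 1], identical alleles) are dropped and
#' counted; input order is preserved for the survivors.
#'
#' @param path Path to a TSV file with a header row.
#' @param column_map Optional named character vector mapping canonical field
#'   names to the file's column names, e.g.
#'   `c(snp_id = "variant_id", pval = "p_value")`. Unmapped canonical names
#'   are looked up verbatim.
#'
#' @return A data frame in the canonical layout, with attribute `n_dropped`
#'   giving the number of invalid rows removed.
#' @export
read_summary_table <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(raw) == 0L) {
    warning("empty summary-statistics file: ", path)
    out <- as.data.frame(stats::setNames(
      lapply(.canonical_cols, function(x) character(0)), .canonical_cols))
    attr(out, "n_dropped") <- 0L
    return(out)
  }
  wanted <- stats::setNames(.canonical_cols, .canonical_cols)
  if (!is.null(column_map)) {
    bad <- setdiff(names(column_map), .canonical_cols)
    if (length(bad)) stop("column_map has unknown fields: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    wanted[names(column_map)] <- column_map
  }
  missing <- wanted[!wanted %in% names(raw)]
  if (length(missing)) {
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  out <- raw[, unname(wanted), drop = FALSE]
  names(out) <- .canonical_cols
  for (col in c("pos", "eaf", "beta", "se", "pval", "n")) {
    out[[col]] <- as.numeric(out[[col]])
  }
  out$snp_id <- as.character(out$snp_id)
  out$chrom <- as.character(out$chrom)
  out$effect_allele <- toupper(as.character(out$effect_allele))
  out$other_allele <- toupper(as.character(out$other_allele))

  ok <- is.finite(out$beta) & is.finite(out$se) & out$se > 0 &
    is.finite(out$pval) & out$pval > 0 & out$pval <= 1 &
    (is.na(out$eaf) | (out$eaf >= 0 & out$eaf <= 1)) &
    out$effect_allele != out$other_allele
  dropped <- sum(!ok)
  if (dropped > 0) {
    warning(sprintf("dropped %d row(s) violating record invariants", dropped))
  }
  out <- out[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- dropped
  out
}

#' Write a summary-statistics table
#'
#' Writes the canonical tab-separated dialect read by [read_summary_table()].
#' Output is bit-stable for fixed input.
#'
#' @param records Data frame in the canonical layout.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary_table <- function(records, path) {
  stopifnot(all(.canonical_cols %in% names(records)))
  utils::write.table(records[, .canonical_cols, drop = FALSE], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Harmonize exposure and outcome summary statistics
#'
#' Aligns outcome records to the exposure's effect-allele orientation for all
#' SNPs present in both inputs. Per shared SNP: identical alleles are kept
#' as-is; swapped alleles flip the outcome beta sign and frequency;
#' complementary (strand-flipped) alleles are complemented first; palindromic
#' (A/T, C/G) SNPs are retained only when both allele frequencies fall on the
#' same side of 0.5 and outside `0.5 +/- palindromic_eaf_window`, with the
#' orientation inferred from frequency; irreconcilable allele sets are
#' dropped.
#'
#' @param exposure,outcome Data frames in the canonical summary layout, keyed
#'   by `snp_id` (duplicates are an error).
#' @param palindromic_eaf_window Half-width of the ambiguous frequency band
#'   around 0.5 within which palindromic SNPs are dropped; in [0, 0.5).
#'   Default 0.08 (drop when either frequency is in [0.42, 0.58]).
#'
#' @return A data frame of class `harmonized_set` with one row per retained
#'   SNP: `snp_id`, `beta_exposure`, `se_exposure`, `beta_outcome`,
#'   `se_outcome`, `eaf_exposure`, `eaf_outcome`, plus attributes `n_flipped`,
#'   `n_dropped_palindromic`, `n_dropped_mismatch`.
#' @export
harmonize <- function(exposure, outcome, palindromic_eaf_window = 0.08) {
  stopifnot(palindromic_eaf_window >= 0, palindromic_eaf_window < 0.5)
  for (nm in c("exposure", "outcome")) {
    tab <- get(nm)
    dup <- unique(tab$snp_id[duplicated(tab$snp_id)])
    if (length(dup)) {
      stop(sprintf("duplicate snp_id in %s input: %s", nm,
                   paste(utils::head(dup, 10), collapse = ", ")),
           call. = FALSE)
    }
  }
  shared <- intersect(exposure$snp_id, outcome$snp_id)
  ex <- exposure[match(shared, exposure$snp_id), , drop = FALSE]
  ou <- outcome[match(shared, outcome$snp_id), , drop = FALSE]

  n <- length(shared)
  keep <- logical(n)
  flip <- logical(n)   # negate outcome beta, eaf <- 1 - eaf
  n_pal_drop <- 0L
  n_mismatch <- 0L

  win_lo <- 0.5 - palindromic_eaf_window
  win_hi <- 0.5 + palindromic_eaf_window

  for (i in seq_len(n)) {
    e1 <- ex$effect_allele[i]; e2 <- ex$other_allele[i]
    o1 <- ou$effect_allele[i]; o2 <- ou$other_allele[i]
    pal <- is_palindromic_pair(e1, e2)
    if (pal) {
      # Letters cannot distinguish strands for A/T and C/G SNPs; allele sets
      # must still agree (as-is or complemented, which coincide here).
      if (!setequal(c(e1, e2), c(o1, o2))) { n_mismatch <- n_mismatch + 1L; next }
      fx <- ex$eaf[i]; fy <- ou$eaf[i]
      # Frequency of the exposure effect allele in the outcome, by letter.
      fy_aligned <- if (o1 == e1) fy else 1 - fy
      if (is.na(fx) || is.na(fy_aligned) ||
          (fx > win_lo && fx < win_hi) ||
          (fy_aligned > win_lo && fy_aligned < win_hi) ||
          # near-0.5 exact boundary counts as ambiguous
          fx == win_lo || fx == win_hi ||
          fy_aligned == win_lo || fy_aligned == win_hi) {
        n_pal_drop <- n_pal_drop + 1L; next
      }
      if ((fx < 0.5) != (fy_aligned < 0.5)) {
        # Frequencies disagree after letter alignment: the letters were read
        # off opposite strands, so the reported effect allele is really the
        # exposure's other allele.
        fy_aligned <- 1 - fy_aligned
        if ((fx < 0.5) != (fy_aligned < 0.5)) { n_pal_drop <- n_pal_drop + 1L; next }
        keep[i] <- TRUE
        flip[i] <- (o1 == e1)   # letter-match said as-is; frequency says swap
      } else {
        keep[i] <- TRUE
        flip[i] <- (o1 != e1)
      }
    } else {
      if (o1 == e1 && o2 == e2) {
        keep[i] <- TRUE
      } else if (o1 == e2 && o2 == e1) {
        keep[i] <- TRUE; flip[i] <- TRUE
      } else {
        c1 <- unname(.complement[o1]); c2 <- unname(.complement[o2])
        if (identical(c1, e1) && identical(c2, e2)) {
          keep[i] <- TRUE
        } else if (identical(c1, e2) && identical(c2, e1)) {
          keep[i] <- TRUE; flip[i] <- TRUE
        } else {
          n_mismatch <- n_mismatch + 1L
        }
      }
    }
  }

  beta_y <- ifelse(flip, -ou$beta, ou$beta)
  eaf_y <- ifelse(flip, 1 - ou$eaf, ou$eaf)

  h <- data.frame(
    snp_id = shared,
    beta_exposure = ex$beta, se_exposure = ex$se,
    beta_outcome = beta_y, se_outcome = ou$se,
    eaf_exposure = ex$eaf, eaf_outcome = eaf_y,
    stringsAsFactors = FALSE
  )[keep, , drop = FALSE]
  rownames(h) <- NULL
  attr(h, "n_flipped") <- sum(flip & keep)
  attr(h, "n_dropped_palindromic") <- n_pal_drop
  attr(h, "n_dropped_mismatch") <- n_mismatch
  class(h) <- c("harmonized_set", "data.frame")
  h
}

#' Build a harmonized set directly from aligned effect vectors
#'
#' Convenience constructor used when exposure and outcome effects are already
#' on a common effect-allele orientation (e.g. simulation output).
#'
#' @param beta_exposure,se_exposure,beta_outcome,se_outcome Numeric vectors of
#'   equal length; all standard errors must be positive.
#' @param snp_id Optional SNP identifiers.
#' @param eaf_exposure,eaf_outcome Optional effect-allele frequencies.
#' @return A `harmonized_set` data frame.
#' @export
harmonized_set <- function(beta_exposure, se_exposure, beta_outcome,
                           se_outcome, snp_id = NULL,
                           eaf_exposure = NA_real_, eaf_outcome = NA_real_) {
  k <- length(beta_exposure)
  stopifnot(length(se_exposure) == k, length(beta_outcome) == k,
            length(se_outcome) == k,
            all(se_exposure > 0), all(se_outcome > 0))
  if (is.null(snp_id)) snp_id <- sprintf("snp%05d", seq_len(k))
  h <- data.frame(snp_id = as.character(snp_id),
                  beta_exposure = beta_exposure, se_exposure = se_exposure,
                  beta_outcome = beta_outcome, se_outcome = se_outcome,
                  eaf_exposure = rep_len(eaf_exposure, k),
                  eaf_outcome = rep_len(eaf_outcome, k),
                  stringsAsFactors = FALSE)
  attr(h, "n_flipped") <- 0L
  attr(h, "n_dropped_palindromic") <- 0L
  attr(h, "n_dropped_mismatch") <- 0L
  class(h) <- c("harmonized_set", "data.frame")
  h
}
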