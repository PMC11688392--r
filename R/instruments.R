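#' Filter records by association p-value
#'
#' Keeps records with p-value strictly below `threshold` (genome-wide
#' significance, default 1e-8). Order is preserved.
#'
#' @param records Canonical summary-statistics data frame.
#' @param threshold Significance threshold in (0, 1).
#' @return The retained records; a warning is raised if none survive.
#' @export
filter_pvalue <- function(records, threshold = 1e-8) {
  stopifnot(threshold > 0, threshold < 1)
  keep <- records$pval < threshold
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  if (nrow(out) == 0L && nrow(records) > 0L) {
    warning("no records pass the p-value threshold ", format(threshold))
  }
  out
}

#' Instrument strength: variance explained and F-statistic
#'
#' Computes per-SNP variance explained R^2 = 2 MAF (1 - MAF) beta^2 and the
#' F-statistic F = R^2 (N - 2) / (1 - R^2), on a standardized-exposure scale.
#' Allele frequencies above 0.5 are folded to the minor allele.
#'
#' @param maf Allele frequency; values > 0.5 are folded to 1 - maf.
#' @param beta Standardized per-allele effect estimate.
#' @param n GWAS sample size (> 2).
#' @return A list with vectors `r2` and `f`.
#' @examples
#' f_statistic(0.3, 0.1, 136016)  # r2 = 0.0042, F ~ 573.7
#' @export
f_statistic <- function(maf, beta, n) {
  stopifnot(all(n > 2))
  maf <- ifelse(maf > 0.5, 1 - maf, maf)
  if (any(!is.na(maf) & maf <= 0)) {
    stop("maf must be in (0, 0.5] after folding", call. = FALSE)
  }
  r2 <- 2 * maf * (1 - maf) * beta^2
  if (any(is.finite(r2) & r2 >= 1)) {
    stop("r2 >= 1: beta inconsistent with a standardized scale", call. = FALSE)
  }
  list(r2 = r2, f = r2 * (n - 2) / (1 - r2))
}

#' Greedy LD clumping
#'
#' Selects approximately independent SNPs: records are sorted by ascending
#' p-value (ties broken lexicographically by `snp_id`), the best remaining
#' SNP is taken as an index, and every other same-chromosome SNP within
#' `window_kb` kilobases whose r^2 with the index is >= `r2_max` is removed.
#' Pairs absent from `pairwise_r2` are treated as r^2 = 0.
#'
#' @param records Canonical summary-statistics data frame with `pos` present.
#' @param pairwise_r2 Data frame with columns `snp_a`, `snp_b`, `r2`
#'   (symmetric; either order accepted), or `NULL` for all-independent.
#' @param window_kb Clumping window in kilobases (default 10,000).
#' @param r2_max LD threshold (default 0.001).
#' @return The retained records in selection (p-value) order.
#' @export
clump <- function(records, pairwise_r2 = NULL, window_kb = 10000,
                  r2_max = 0.001) {
  if (nrow(records) == 0L) return(records)
  if (any(is.na(records$pos))) {
    stop("clump: missing pos on one or more records", call. = FALSE)
  }
  ord <- order(records$pval, records$snp_id)
  rec <- records[ord, , drop = FALSE]

  r2_lookup <- function(a, b) {
    if (is.null(pairwise_r2) || nrow(pairwise_r2) == 0L) return(0)
    hit <- (pairwise_r2$snp_a == a & pairwise_r2$snp_b == b) |
      (pairwise_r2$snp_a == b & pairwise_r2$snp_b == a)
    if (any(hit)) max(pairwise_r2$r2[hit]) else 0
  }

  window_bp <- window_kb * 1000
  alive <- rep(TRUE, nrow(rec))
  selected <- integer(0)
  for (i in seq_len(nrow(rec))) {
    if (!alive[i]) next
    selected <- c(selected, i)
    same_chr <- alive & rec$chrom == rec$chrom[i] &
      abs(rec$pos - rec$pos[i]) <= window_bp
    same_chr[i] <- FALSE
    for (j in which(same_chr)) {
      if (r2_lookup(rec$snp_id[i], rec$snp_id[j]) >= r2_max) alive[j] <- FALSE
    }
    alive[i] <- FALSE
  }
  out <- rec[selected, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exclude weak instruments by F-statistic
#'
#' Keeps records whose F-statistic is at least `f_min`; only F < 10 marks a
#' weak instrument, so the boundary F = 10 is retained.
#'
#' @param records Canonical records with a numeric `f` column attached.
#' @param f_min Weak-instrument threshold (default 10).
#' @return The retained records.
#' @export
filter_weak <- function(records, f_min = 10) {
  stopifnot("f" %in% names(records))
  out <- records[records$f >= f_min, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Full instrument-selection chain
#'
#' Applies, in order: genome-wide significance filtering, greedy LD clumping,
#' and F-statistic weak-instrument exclusion, attaching per-SNP `r2` and `f`
#' columns (computed from the exposure association with folded MAF). Records
#' with missing allele frequency are excluded from the F filter with a
#' warning, since variance explained needs the MAF.
#'
#' @param records Exposure summary-statistics records.
#' @param pairwise_r2 Optional LD table, see [clump()].
#' @param pval_threshold Significance threshold (default 1e-8).
#' @param window_kb,r2_max Clumping parameters.
#' @param f_min Weak-instrument threshold.
#' @return A data frame of retained instruments with `r2` and `f` columns and
#'   attribute `audit`, a named integer vector of exclusion counts
#'   (`n_failed_pval`, `n_clumped_out`, `n_weak`).
#' @export
select_instruments <- function(records, pairwise_r2 = NULL,
                               pval_threshold = 1e-8, window_kb = 10000,
                               r2_max = 0.001, f_min = 10) {
  n0 <- nrow(records)
  sig <- filter_pvalue(records, pval_threshold)
  n1 <- nrow(sig)
  clumped <- clump(sig, pairwise_r2, window_kb = window_kb, r2_max = r2_max)
  n2 <- nrow(clumped)
  if (n2 > 0) {
    no_eaf <- is.na(clumped$eaf)
    if (any(no_eaf)) {
      warning(sprintf(
        "%d record(s) lack eaf and are excluded from the F-statistic filter",
        sum(no_eaf)))
    }
    st <- f_statistic(clumped$eaf, clumped$beta, clumped$n)
    clumped$r2 <- st$r2
    clumped$f <- st$f
    # Records without eaf cannot be assessed for strength; they are retained
    # for estimation rather than silently discarded.
    kept <- rbind(filter_weak(clumped[!no_eaf, , drop = FALSE], f_min),
                  clumped[no_eaf, , drop = FALSE])
    kept <- kept[order(match(kept$snp_id, clumped$snp_id)), , drop = FALSE]
  } else {
    clumped$r2 <- numeric(0)
    clumped$f <- numeric(0)
    kept <- clumped
  }
  rownames(kept) <- NULL
  attr(kept, "audit") <- c(n_failed_pval = n0 - n1,
                           n_clumped_out = n1 - n2,
                           n_weak = n2 - nrow(kept))
  kept
}
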