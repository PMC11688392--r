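#' Cochran's Q heterogeneity statistic
#'
#' Q = sum_j w_j (by_j - b * bx_j)^2 with weights 1/se_outcome^2, referred to
#' a chi-square distribution on k - 1 degrees of freedom. Evaluated at the
#' fixed-effect IVW slope unless `b_ivw` is supplied.
#'
#' @param h A `harmonized_set` with k >= 2 instruments.
#' @param b_ivw Slope at which to evaluate Q; defaults to the fixed-effect
#'   IVW estimate.
#' @return A list with `q`, `df`, `pval`.
#' @export
cochran_q <- function(h, b_ivw = NULL) {
  k <- nrow(h)
  if (k < 2) stop("cochran_q: at least 2 instruments required", call. = FALSE)
  if (is.null(b_ivw)) b_ivw <- mr_ivw(h, model = "fixed")$b
  w <- 1 / h$se_outcome^2
  q <- sum(w * (h$beta_outcome - b_ivw * h$beta_exposure)^2)
  df <- k - 1
  list(q = q, df = df, pval = stats::pchisq(q, df, lower.tail = FALSE))
}

#' Fixed/random IVW model selection from heterogeneity
#'
#' Heterogeneity (Q p-value < 0.05) calls for the random-effects IVW model;
#' otherwise the fixed-effect model is used.
#'
#' @param q A result from [cochran_q()].
#' @param alpha Heterogeneity significance level (default 0.05).
#' @return `"random"` or `"fixed"`.
#' @export
heterogeneity_policy <- function(q, alpha = 0.05) {
  if (q$pval < alpha) "random" else "fixed"
}

#' MR-Egger intercept test for horizontal pleiotropy
#'
#' Flags directional pleiotropy when the Egger intercept differs from zero
#' (p <= 0.05 by default).
#'
#' @param fit An `egger_fit` from [mr_egger()].
#' @param alpha Significance level.
#' @return A list with `pleiotropy_present` and `pval`.
#' @export
egger_intercept_test <- function(fit, alpha = 0.05) {
  list(pleiotropy_present = fit$intercept_pval <= alpha,
       pval = fit$intercept_pval)
}

# Leave-one-out fixed-effect IVW slopes in O(k) from running sums.
loo_ivw_slopes <- function(bx, by, w) {
  s_xy <- sum(w * bx * by)
  s_xx <- sum(w * bx^2)
  (s_xy - w * bx * by) / (s_xx - w * bx^2)
}

#' MR-PRESSO outlier detection and correction
#'
#' Simulation-based residual-sum-of-squares test for pleiotropic outliers.
#' The observed global statistic is `RSS = sum_j w_j (by_j - b_(-j) bx_j)^2`
#' using leave-one-out IVW slopes `b_(-j)`; its null distribution comes from
#' `n_sim` parametric simulations drawing `by*_j ~ N(b_(-j) bx_j, se_y_j)`
#' and `bx*_j ~ N(bx_j, se_x_j)` and recomputing the statistic. Per-SNP
#' outlier p-values compare each observed residual contribution with its
#' simulated counterpart, Bonferroni-adjusted by k; the distortion test
#' compares the change in the IVW estimate after removing outliers against
#' removals of equally many random instruments.
#'
#' @param h A `harmonized_set` with k >= 4 instruments.
#' @param n_sim Number of null simulations (>= 1000).
#' @param seed RNG seed (required for reproducibility).
#' @param outlier_alpha Bonferroni-adjusted significance level for declaring
#'   outliers.
#' @return A list with `global_rss`, `global_pval`, `outlier_pvals`
#'   (Bonferroni-adjusted, named by SNP), `outliers` (character vector of
#'   SNP ids), `distortion_pval` (`NA` when no outliers are found), and
#'   `corrected`, the fixed-effect IVW `mr_estimate` on the non-outliers
#'   (`NULL` if fewer than 2 remain).
#' @export
mr_presso <- function(h, n_sim = 1000, seed = 1L, outlier_alpha = 0.05) {
  k <- nrow(h)
  if (k < 4) stop("mr_presso: at least 4 instruments required", call. = FALSE)
  if (n_sim < 1000) stop("mr_presso: n_sim must be >= 1000", call. = FALSE)
  set.seed(seed)

  bx <- h$beta_exposure; by <- h$beta_outcome
  sx <- h$se_exposure; sy <- h$se_outcome
  w <- 1 / sy^2

  b_loo <- loo_ivw_slopes(bx, by, w)
  contrib_obs <- w * (by - b_loo * bx)^2
  rss_obs <- sum(contrib_obs)

  # Null simulations, vectorized over replicates (k x n_sim matrices).
  bx_sim <- matrix(stats::rnorm(k * n_sim, bx, sx), nrow = k)
  by_sim <- matrix(stats::rnorm(k * n_sim, b_loo * bx, sy), nrow = k)
  s_xy <- colSums(w * bx_sim * by_sim)
  s_xx <- colSums(w * bx_sim^2)
  b_loo_sim <- (matrix(s_xy, k, n_sim, byrow = TRUE) - w * bx_sim * by_sim) /
    (matrix(s_xx, k, n_sim, byrow = TRUE) - w * bx_sim^2)
  contrib_sim <- w * (by_sim - b_loo_sim * bx_sim)^2
  rss_sim <- colSums(contrib_sim)

  global_pval <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)

  outlier_raw <- (1 + rowSums(contrib_sim >= contrib_obs)) / (n_sim + 1)
  outlier_adj <- pmin(1, outlier_raw * k)
  names(outlier_adj) <- h$snp_id
  outliers <- h$snp_id[outlier_adj < outlier_alpha]

  distortion_pval <- NA_real_
  corrected <- NULL
  keep <- !(h$snp_id %in% outliers)
  if (sum(keep) >= 2) {
    corrected <- mr_ivw(h[keep, , drop = FALSE], model = "fixed")
  }
  if (length(outliers) > 0 && sum(keep) >= 2) {
    b_all <- mr_ivw(h, model = "fixed")$b
    d_obs <- abs(corrected$b - b_all)
    n_out <- length(outliers)
    d_null <- vapply(seq_len(n_sim), function(i) {
      drop_idx <- sample.int(k, n_out)
      hh <- h[-drop_idx, , drop = FALSE]
      abs(mr_ivw(hh, model = "fixed")$b - b_all)
    }, numeric(1))
    distortion_pval <- (1 + sum(d_null >= d_obs)) / (n_sim + 1)
  }

  list(global_rss = rss_obs, global_pval = global_pval,
       outlier_pvals = outlier_adj, outliers = outliers,
       distortion_pval = distortion_pval, corrected = corrected)
}

#' Steiger directionality test
#'
#' Compares the variance the instruments explain in the exposure with the
#' variance they explain in the outcome. Per-trait R^2 is summed over
#' instruments using `2 eaf (1 - eaf) beta^2` on each trait's own scale
#' (frequencies folded to the minor allele); the p-value for the difference
#' of the implied correlations uses Fisher's z transformation with the two
#' sample sizes. The assumed exposure-to-outcome direction is supported when
#' `direction_correct` is `TRUE` *and* the p-value is small.
#'
#' @param h A `harmonized_set` with exposure frequencies available.
#' @param n_exposure,n_outcome Trait sample sizes (> 3).
#' @return A list with `r2_exposure`, `r2_outcome`, `direction_correct`,
#'   `pval`.
#' @export
steiger <- function(h, n_exposure, n_outcome) {
  stopifnot(n_exposure > 3, n_outcome > 3)
  fold <- function(f) ifelse(f > 0.5, 1 - f, f)
  fx <- fold(h$eaf_exposure)
  fy <- fold(ifelse(is.na(h$eaf_outcome), h$eaf_exposure, h$eaf_outcome))
  if (any(is.na(fx))) {
    stop("steiger: exposure allele frequencies required", call. = FALSE)
  }
  r2_exp <- sum(2 * fx * (1 - fx) * h$beta_exposure^2)
  r2_out <- sum(2 * fy * (1 - fy) * h$beta_outcome^2)
  if (r2_exp >= 1 || r2_out >= 1) {
    stop("steiger: summed r2 >= 1; effects inconsistent with standardized scale",
         call. = FALSE)
  }
  z <- (atanh(sqrt(r2_exp)) - atanh(sqrt(r2_out))) /
    sqrt(1 / (n_exposure - 3) + 1 / (n_outcome - 3))
  list(r2_exposure = r2_exp, r2_outcome = r2_out,
       direction_correct = r2_exp > r2_out,
       pval = two_sided_p(z))
}

#' Leave-one-out IVW analysis
#'
#' Recomputes the fixed-effect IVW estimate with each instrument removed in
#' turn; flags the analysis unstable if any reduced-set estimate changes sign
#' relative to the full estimate or its confidence interval excludes it.
#'
#' @param h A `harmonized_set` with k >= 3 instruments.
#' @param level Confidence level for the stability check.
#' @return A data frame with one row per dropped SNP (`snp_id`, `b`, `se`,
#'   `pval`) and attribute `unstable` (logical).
#' @export
leave_one_out <- function(h, level = 0.95) {
  k <- nrow(h)
  if (k < 3) stop("leave_one_out: at least 3 instruments required",
                  call. = FALSE)
  full <- mr_ivw(h, model = "fixed")
  rows <- lapply(seq_len(k), function(j) {
    est <- mr_ivw(h[-j, , drop = FALSE], model = "fixed")
    data.frame(snp_id = h$snp_id[j], b = est$b, se = est$se, pval = est$pval,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  z <- stats::qnorm(1 - (1 - level) / 2)
  excl <- (full$b < out$b - z * out$se) | (full$b > out$b + z * out$se)
  attr(out, "unstable") <- any(sign(out$b) != sign(full$b) | excl)
  out
}

#' Funnel-plot data
#'
#' Per-SNP Wald ratios against their precision (1 / ratio standard error);
#' plot-ready, no graphics.
#'
#' @param h A `harmonized_set`.
#' @return A data frame with `snp_id`, `ratio`, `precision`.
#' @export
funnel_data <- function(h) {
  rw <- ratio_weights(h)
  data.frame(snp_id = h$snp_id, ratio = rw$ratios,
             precision = sqrt(rw$weights), stringsAsFactors = FALSE)
}
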