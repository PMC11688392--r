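#' Per-SNP Wald ratio
#'
#' The single-variant causal estimate: outcome effect divided by exposure
#' effect, with the first-order standard error `sy / |bx|` (exposure-side
#' sampling error ignored, matching the inverse-variance weighting used
#' throughout).
#'
#' @param bx,sx Exposure effect and standard error.
#' @param by,sy Outcome effect and standard error.
#' @return A list with `ratio` and `se`.
#' @export
wald_ratio <- function(bx, sx, by, sy) {
  if (any(bx == 0)) stop("wald_ratio: bx must be nonzero", call. = FALSE)
  list(ratio = by / bx, se = sy / abs(bx))
}

new_mr_estimate <- function(method, nsnp, b, se, model = NA_character_,
                            level = 0.95) {
  or <- to_or(b, se, level)
  structure(list(method = method, nsnp = as.integer(nsnp), b = b, se = se,
                 pval = p_from_z(b, se), or_ = or$or_, ci_low = or$ci_low,
                 ci_high = or$ci_high, model = model),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf(
    "MR estimate [%s%s]  nsnp=%d\n  b=%.6g  se=%.6g  p=%.3g  OR=%.4g (%.4g, %.4g)\n",
    x$method, if (!is.na(x$model)) paste0(", ", x$model) else "",
    x$nsnp, x$b, x$se, x$pval, x$or_, x$ci_low, x$ci_high))
  invisible(x)
}

#' Inverse-variance weighted estimator
#'
#' The primary causal estimator: a precision-weighted combination of per-SNP
#' Wald ratios, equivalent to weighted regression of the outcome effects on
#' the exposure effects through the origin with weights 1/se_outcome^2. The
#' fixed-effect standard error is `sqrt(1 / sum(w bx^2))`; the random-effects
#' (multiplicative) variant scales it by `max(1, sqrt(Q / (k - 1)))` with
#' Cochran's Q evaluated at the slope.
#'
#' @param h A `harmonized_set`.
#' @param model `"fixed"` or `"random"`.
#' @param level Confidence level for the odds-ratio interval.
#' @return An `mr_estimate`. With a single instrument the estimate degrades
#'   to the Wald ratio with a warning.
#' @export
mr_ivw <- function(h, model = c("fixed", "random"), level = 0.95) {
  model <- match.arg(model)
  k <- nrow(h)
  if (k < 1) stop("mr_ivw: empty instrument set", call. = FALSE)
  bx <- h$beta_exposure; by <- h$beta_outcome; sy <- h$se_outcome
  if (all(bx == 0)) stop("mr_ivw: all exposure effects are zero", call. = FALSE)
  if (k == 1L) {
    warning("single instrument: IVW degrades to the Wald ratio")
    wr <- wald_ratio(bx, h$se_exposure, by, sy)
    return(new_mr_estimate("wald", 1L, wr$ratio, wr$se, model, level))
  }
  w <- 1 / sy^2
  denom <- sum(w * bx^2)
  b <- sum(w * bx * by) / denom
  se_fixed <- sqrt(1 / denom)
  se <- se_fixed
  if (model == "random") {
    q <- sum(w * (by - b * bx)^2)
    se <- se_fixed * max(1, sqrt(q / (k - 1)))
  }
  new_mr_estimate("ivw", k, b, se, model, level)
}

#' MR-Egger regression
#'
#' Weighted least-squares regression of outcome on exposure effects with an
#' unconstrained intercept (weights 1/se_outcome^2). The slope is a
#' pleiotropy-adjusted causal estimate; the intercept estimates average
#' directional pleiotropy. Rows are pre-oriented so every exposure effect is
#' non-negative (both betas negated where needed), since the fit is not
#' invariant to allele orientation. Standard errors use the weighted
#' least-squares covariance with the residual scale floored at 1
#' (`max(1, sqrt(RSS / (k - 2)))`); p-values use the normal reference.
#'
#' @param h A `harmonized_set` with at least 3 instruments.
#' @param level Confidence level.
#' @return A list of class `egger_fit`: `slope` (an `mr_estimate`),
#'   `intercept`, `intercept_se`, `intercept_pval`.
#' @export
mr_egger <- function(h, level = 0.95) {
  k <- nrow(h)
  if (k < 3) stop("mr_egger: at least 3 instruments required", call. = FALSE)
  flip <- h$beta_exposure < 0
  bx <- abs(h$beta_exposure)
  by <- ifelse(flip, -h$beta_outcome, h$beta_outcome)
  w <- 1 / h$se_outcome^2
  x <- cbind(1, bx)
  xtwx_inv <- solve(crossprod(x, w * x))
  est <- drop(xtwx_inv %*% crossprod(x, w * by))
  rss <- sum(w * (by - drop(x %*% est))^2)
  # Residual scale floored at 1: under-dispersed data must not shrink the
  # standard errors below the fixed-effect ones.
  sigma <- max(1, sqrt(rss / (k - 2)))
  ses <- sqrt(diag(xtwx_inv)) * sigma
  int <- unname(est[1]); slope <- unname(est[2])
  int_se <- unname(ses[1]); slope_se <- unname(ses[2])
  structure(list(
    slope = new_mr_estimate("egger", k, slope, slope_se, NA_character_, level),
    intercept = int, intercept_se = int_se,
    intercept_pval = p_from_z(int, int_se)
  ), class = "egger_fit")
}

weighted_median_point <- function(ratios, weights) {
  ord <- order(ratios)
  r <- ratios[ord]
  w <- weights[ord] / sum(weights)
  cum <- cumsum(w) - 0.5 * w
  if (cum[1] >= 0.5) return(r[1])
  below <- max(which(cum < 0.5))
  if (below == length(r)) return(r[length(r)])
  r[below] + (r[below + 1] - r[below]) *
    (0.5 - cum[below]) / (cum[below + 1] - cum[below])
}

ratio_weights <- function(h) {
  if (any(h$beta_exposure == 0)) {
    bad <- h$snp_id[h$beta_exposure == 0]
    stop("zero exposure effect for SNP(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  ratios <- h$beta_outcome / h$beta_exposure
  se_ratio <- h$se_outcome / abs(h$beta_exposure)
  list(ratios = ratios, weights = 1 / se_ratio^2)
}

bootstrap_se <- function(h, point_fun, n_boot, seed) {
  set.seed(seed)
  k <- nrow(h)
  est <- vapply(seq_len(n_boot), function(i) {
    hb <- h
    hb$beta_exposure <- stats::rnorm(k, h$beta_exposure, h$se_exposure)
    hb$beta_outcome <- stats::rnorm(k, h$beta_outcome, h$se_outcome)
    point_fun(hb)
  }, numeric(1))
  stats::sd(est)
}

#' Weighted median estimator
#'
#' Consistent when at least half the weight comes from valid instruments.
#' Per-SNP Wald ratios are sorted and the estimate is the value at which the
#' half-weight-interpolated cumulative weight crosses one half; the standard
#' error comes from a parametric bootstrap perturbing both effect vectors by
#' their standard errors.
#'
#' @param h A `harmonized_set` with at least 3 instruments and no zero
#'   exposure effects.
#' @param n_boot Bootstrap replicates for the standard error (default 1000).
#' @param seed RNG seed for the bootstrap (required for reproducibility).
#' @param level Confidence level.
#' @return An `mr_estimate`.
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed = 1L, level = 0.95) {
  k <- nrow(h)
  if (k < 3) stop("mr_weighted_median: at least 3 instruments required",
                  call. = FALSE)
  point <- function(hh) {
    rw <- ratio_weights(hh)
    weighted_median_point(rw$ratios, rw$weights)
  }
  b <- point(h)
  se <- bootstrap_se(h, function(hh) {
    hh$beta_exposure[hh$beta_exposure == 0] <- .Machine$double.eps
    point(hh)
  }, n_boot, seed)
  new_mr_estimate("weighted_median", k, b, se, NA_character_, level)
}

weighted_mode_point <- function(ratios, weights, bandwidth_factor = 1) {
  k <- length(ratios)
  spread <- min(stats::sd(ratios), stats::IQR(ratios) / 1.349)
  if (!is.finite(spread) || spread == 0) {
    if (length(unique(ratios)) == 1L) return(ratios[1])
    spread <- stats::sd(ratios)          # degenerate IQR with distinct values
    if (spread == 0) return(ratios[1])
  }
  h_bw <- bandwidth_factor * 0.9 * spread * k^(-1 / 5)
  grid <- seq(min(ratios) - 3 * h_bw, max(ratios) + 3 * h_bw, length.out = 512)
  dens <- vapply(grid, function(g) {
    sum(weights * stats::dnorm(g, ratios, h_bw))
  }, numeric(1))
  grid[which.max(dens)]
}

#' Weighted mode estimator
#'
#' Consistent when the largest homogeneous cluster of instruments is valid.
#' The estimate is the maximizer of a normal-kernel-smoothed, weight-scaled
#' density of the per-SNP Wald ratios, with bandwidth
#' `bandwidth_factor * 0.9 * min(SD, IQR/1.349) * k^(-1/5)` evaluated on a
#' fixed 512-point grid spanning the ratio range plus three bandwidths.
#' Standard error by parametric bootstrap, as in [mr_weighted_median()].
#'
#' @inheritParams mr_weighted_median
#' @param bandwidth_factor Multiplier on the default kernel bandwidth (> 0).
#' @return An `mr_estimate`.
#' @export
mr_weighted_mode <- function(h, bandwidth_factor = 1, n_boot = 1000,
                             seed = 1L, level = 0.95) {
  k <- nrow(h)
  if (k < 3) stop("mr_weighted_mode: at least 3 instruments required",
                  call. = FALSE)
  stopifnot(bandwidth_factor > 0)
  point <- function(hh) {
    rw <- ratio_weights(hh)
    weighted_mode_point(rw$ratios, rw$weights, bandwidth_factor)
  }
  b <- point(h)
  se <- bootstrap_se(h, function(hh) {
    hh$beta_exposure[hh$beta_exposure == 0] <- .Machine$double.eps
    point(hh)
  }, n_boot, seed)
  new_mr_estimate("weighted_mode", k, b, se, NA_character_, level)
}

#' Log-odds estimate to odds ratio with confidence interval
#'
#' @param b Log-odds causal estimate.
#' @param se Standard error (> 0).
#' @param level Confidence level (default 0.95).
#' @return A list with `or_`, `ci_low`, `ci_high`.
#' @examples
#' to_or(-0.216673334, 0.068095147)  # OR ~ 0.8052
#' @export
to_or <- function(b, se, level = 0.95) {
  stopifnot(all(se > 0))
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(or_ = exp(b), ci_low = exp(b - z * se), ci_high = exp(b + z * se))
}

#' Two-sided normal p-value for an estimate
#'
#' @param b Estimate.
#' @param se Standard error (> 0).
#' @return `2 * pnorm(-abs(b / se))`, floored at the smallest positive double.
#' @export
p_from_z <- function(b, se) {
  stopifnot(all(se > 0))
  two_sided_p(b / se)
}
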