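#' Configuration for the synthetic two-sample GWAS generator
#'
#' Builds and validates the parameter set for [simulate_gwas_pair()]. Defaults
#' emulate a large metabolite GWAS (continuous exposure, 136,016 participants)
#' and a breast-cancer-scale case-control outcome GWAS (122,977 cases,
#' 105,974 controls).
#'
#' The generative model, per candidate SNP j with minor-allele frequency
#' p_j ~ Uniform(maf_low, maf_high):
#' \itemize{
#'   \item true SNP-exposure effect gamma_j ~ Normal(0, gamma_sd^2)
#'     (standardized exposure units);
#'   \item direct (pleiotropic) SNP-outcome effect alpha_j, drawn
#'     Normal(alpha_mean, alpha_sd^2) for a `pleio_frac` fraction of SNPs and
#'     zero otherwise; with `inside_violated = TRUE` the pleiotropic effects
#'     are correlated with gamma_j (InSIDE assumption broken);
#'   \item true outcome effect Gamma_j = theta * gamma_j + alpha_j (log-odds);
#'   \item with `reverse_theta != 0` the exposure additionally inherits
#'     reverse_theta * alpha_j, so variants acting directly on the outcome
#'     feed back into the exposure (a reverse-causation scenario for the
#'     Steiger test).
#' }
#' Sampling noise follows the standard summary-statistics approximations:
#' the exposure standard error is 1/sqrt(2 p (1-p) n_exposure) and the
#' outcome (log-odds) standard error 1/sqrt(2 p (1-p) n_eff) with effective
#' sample size n_eff = 4 / (1/n_cases + 1/n_controls).
#'
#' @param m_snps Number of candidate instruments (>= 1).
#' @param n_exposure Exposure GWAS sample size.
#' @param n_cases,n_controls Outcome case-control sample sizes.
#' @param maf_low,maf_high Uniform minor-allele-frequency bounds, in (0, 0.5].
#' @param gamma_sd SD of the true SNP-exposure effects (standardized units).
#' @param theta True causal effect of the exposure on the outcome log-odds.
#' @param alpha_mean,alpha_sd Mean and SD of the direct pleiotropic effects.
#' @param pleio_frac Fraction of SNPs carrying a pleiotropic effect, in [0, 1].
#' @param inside_violated Logical; correlate pleiotropy with instrument
#'   strength (violates the InSIDE assumption behind MR-Egger).
#' @param inside_rho Correlation used when `inside_violated = TRUE`.
#' @param reverse_theta True outcome-to-exposure effect for reverse-causation
#'   scenarios.
#' @param palindromic_frac Fraction of SNPs assigned strand-ambiguous (A/T or
#'   C/G) allele pairs, to exercise the harmonization policy.
#' @param seed Integer RNG seed; identical config and seed give bit-identical
#'   output.
#'
#' @return A validated list of class `synthetic_config`.
#' @seealso [simulate_gwas_pair()]
#' @export
synthetic_config <- function(m_snps = 50,
                             n_exposure = 136016,
                             n_cases = 122977,
                             n_controls = 105974,
                             maf_low = 0.05,
                             maf_high = 0.5,
                             gamma_sd = 0.05,
                             theta = 0,
                             alpha_mean = 0,
                             alpha_sd = 0,
                             pleio_frac = 1,
                             inside_violated = FALSE,
                             inside_rho = 0.5,
                             reverse_theta = 0,
                             palindromic_frac = 0.1,
                             seed = 1L) {
  cfg <- list(
    m_snps = m_snps, n_exposure = n_exposure, n_cases = n_cases,
    n_controls = n_controls, maf_low = maf_low, maf_high = maf_high,
    gamma_sd = gamma_sd, theta = theta, alpha_mean = alpha_mean,
    alpha_sd = alpha_sd, pleio_frac = pleio_frac,
    inside_violated = isTRUE(inside_violated), inside_rho = inside_rho,
    reverse_theta = reverse_theta, palindromic_frac = palindromic_frac,
    seed = as.integer(seed)
  )
  validate_synthetic_config(cfg)
  class(cfg) <- "synthetic_config"
  cfg
}

validate_synthetic_config <- function(cfg) {
  num_fields <- setdiff(names(cfg), "inside_violated")
  for (f in num_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop(sprintf("synthetic_config: field '%s' must be a finite number", f),
           call. = FALSE)
    }
  }
  chk <- function(ok, field, msg) {
    if (!ok) stop(sprintf("synthetic_config: field '%s' %s", field, msg),
                  call. = FALSE)
  }
  chk(cfg$m_snps >= 1, "m_snps", "must be >= 1")
  chk(cfg$n_exposure >= 2, "n_exposure", "must be >= 2")
  chk(cfg$n_cases >= 2, "n_cases", "must be >= 2")
  chk(cfg$n_controls >= 2, "n_controls", "must be >= 2")
  chk(cfg$maf_low > 0, "maf_low", "must be > 0")
  chk(cfg$maf_high <= 0.5, "maf_high", "must be <= 0.5")
  chk(cfg$maf_low <= cfg$maf_high, "maf_low", "must be <= maf_high")
  chk(cfg$gamma_sd >= 0, "gamma_sd", "must be >= 0")
  chk(cfg$alpha_sd >= 0, "alpha_sd", "must be >= 0")
  chk(cfg$pleio_frac >= 0 && cfg$pleio_frac <= 1, "pleio_frac",
      "must be in [0, 1]")
  chk(cfg$palindromic_frac >= 0 && cfg$palindromic_frac <= 1,
      "palindromic_frac", "must be in [0, 1]")
  invisible(cfg)
}

# SNPs are placed 20,000 kb apart on one chromosome so that the default
# 10,000 kb clumping window never merges them: independence by construction.
.synthetic_spacing_bp <- 2e7

#' Simulate a two-sample GWAS summary-statistics pair with known truth
#'
#' Draws exposure and outcome summary-statistics tables under the generative
#' model described in [synthetic_config()], together with the generating
#' parameters, so that instrument selection, harmonization, estimation and
#' every diagnostic can be tested against ground truth.
#'
#' Emitted p-values are exactly `2 * pnorm(-abs(beta / se))` and are
#' recomputable from the emitted columns. Alleles are drawn from {A, C, G, T}
#' with a configurable strand-ambiguous (palindromic) fraction; both tables
#' report the same effect allele and frequency, leaving harmonization a
#' no-flip pass unless records are perturbed downstream.
#'
#' @param config A `synthetic_config` object.
#'
#' @return A list with elements `exposure` and `outcome` (data frames in the
#'   canonical summary-statistics layout used by [read_summary_table()]) and
#'   `truth`, a list with per-SNP `maf`, `gamma`, `alpha`, and scalars
#'   `theta`, `reverse_theta`.
#' @examples
#' sim <- simulate_gwas_pair(synthetic_config(m_snps = 10, seed = 7))
#' head(sim$exposure)
#' sim$truth$theta
#' @export
simulate_gwas_pair <- function(config) {
  if (!inherits(config, "synthetic_config")) {
    config <- do.call(synthetic_config, as.list(config))
  }
  validate_synthetic_config(config)
  m <- as.integer(config$m_snps)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  maf <- stats::runif(m, config$maf_low, config$maf_high)
  gamma <- stats::rnorm(m, 0, config$gamma_sd)

  alpha <- rep(0, m)
  has_pleio <- stats::runif(m) < config$pleio_frac
  n_p <- sum(has_pleio)
  if (n_p > 0 && (config$alpha_mean != 0 || config$alpha_sd != 0)) {
    if (config$inside_violated) {
      # Correlate pleiotropy with instrument strength: alpha tracks gamma
      # (scaled to alpha_sd) plus independent noise.
      scale <- if (config$gamma_sd > 0) config$alpha_sd / config$gamma_sd else 0
      alpha[has_pleio] <- config$alpha_mean +
        config$inside_rho * scale * gamma[has_pleio] +
        sqrt(max(0, 1 - config$inside_rho^2)) *
          stats::rnorm(n_p, 0, config$alpha_sd)
    } else {
      alpha[has_pleio] <- stats::rnorm(n_p, config$alpha_mean, config$alpha_sd)
    }
  }

  gamma_exposure <- gamma + config$reverse_theta * alpha
  big_gamma <- config$theta * gamma + alpha

  n_eff <- 4 / (1 / config$n_cases + 1 / config$n_controls)
  se_x <- 1 / sqrt(2 * maf * (1 - maf) * config$n_exposure)
  se_y <- 1 / sqrt(2 * maf * (1 - maf) * n_eff)

  beta_x <- stats::rnorm(m, gamma_exposure, se_x)
  beta_y <- stats::rnorm(m, big_gamma, se_y)

  is_pal <- stats::runif(m) < config$palindromic_frac
  pal_pairs <- matrix(c("A", "T", "T", "A", "C", "G", "G", "C"),
                      ncol = 2, byrow = TRUE)
  nonpal_pairs <- matrix(c("A", "C", "A", "G", "C", "A", "C", "T",
                           "G", "A", "G", "T", "T", "C", "T", "G"),
                         ncol = 2, byrow = TRUE)
  ea <- oa <- character(m)
  idx_pal <- sample.int(4, m, replace = TRUE)
  idx_non <- sample.int(8, m, replace = TRUE)
  ea[is_pal] <- pal_pairs[idx_pal[is_pal], 1]
  oa[is_pal] <- pal_pairs[idx_pal[is_pal], 2]
  ea[!is_pal] <- nonpal_pairs[idx_non[!is_pal], 1]
  oa[!is_pal] <- nonpal_pairs[idx_non[!is_pal], 2]

  snp_id <- sprintf("snp%05d", seq_len(m))
  pos <- seq_len(m) * .synthetic_spacing_bp

  mk <- function(beta, se, n) {
    data.frame(
      snp_id = snp_id, chrom = "1", pos = pos,
      effect_allele = ea, other_allele = oa, eaf = maf,
      beta = beta, se = se,
      pval = two_sided_p(beta / se),
      n = n, stringsAsFactors = FALSE
    )
  }

  list(
    exposure = mk(beta_x, se_x, config$n_exposure),
    outcome = mk(beta_y, se_y, config$n_cases + config$n_controls),
    truth = list(maf = maf, gamma = gamma, alpha = alpha,
                 theta = config$theta, reverse_theta = config$reverse_theta)
  )
}

# Two-sided normal p-value, kept strictly in (0, 1].
two_sided_p <- function(z) {
  p <- 2 * stats::pnorm(-abs(z))
  pmax(p, .Machine$double.xmin)
}
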