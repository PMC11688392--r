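test_that("wald ratio arithmetic and symmetry", {
  wr <- wald_ratio(0.1, 0.01, 0.05, 0.01)
  expect_equal(wr$ratio, 0.5)
  expect_equal(wr$se, 0.1)
  expect_equal(wald_ratio(0.1, 0.01, 0, 0.02)$ratio, 0)
  expect_equal(wald_ratio(0.1, 0.01, 0, 0.02)$se, 0.2)
  neg <- wald_ratio(-0.1, 0.01, -0.05, 0.01)
  expect_equal(neg$ratio, 0.5)
  expect_error(wald_ratio(0, 0.01, 0.1, 0.01), "nonzero")
})

test_that("IVW reproduces the weighted-regression formulas", {
  h <- make_h(bx = c(1, 1), by = c(0.2, 0.4), sy = c(0.1, 0.1))
  est <- mr_ivw(h, model = "fixed")
  expect_equal(est$b, 0.3)
  expect_equal(est$se, 0.1 / sqrt(2))
  expect_equal(est$pval, 2 * pnorm(-0.3 / (0.1 / sqrt(2))))
  expect_equal(est$or_, exp(0.3))

  # identical ratios: Q = 0, fixed and random agree
  h2 <- make_h(bx = c(1, 2, 4), by = c(0.3, 0.6, 1.2),
               sy = c(0.1, 0.2, 0.1))
  expect_equal(mr_ivw(h2, model = "fixed")$b, 0.3)
  expect_equal(mr_ivw(h2, model = "random")$se,
               mr_ivw(h2, model = "fixed")$se)

  # random-effects se inflates under heterogeneity
  expect_gt(mr_ivw(h, model = "random")$se, est$se)

  expect_error(mr_ivw(make_h(c(0, 0), c(0.1, 0.2), c(0.1, 0.1))), "zero")
  expect_warning(one <- mr_ivw(make_h(1, 0.2, 0.1)), "single")
  expect_equal(one$b, 0.2)
})

test_that("IVW equals the precision-weighted mean of Wald ratios", {
  set.seed(101)
  for (i in 1:100) {
    k <- sample(2:12, 1)
    h <- make_h(bx = rnorm(k, 0, 0.5) + sign(rnorm(k)) * 0.1,
                by = rnorm(k, 0, 0.1),
                sy = runif(k, 0.01, 0.2),
                sx = runif(k, 0.01, 0.05))
    ratios <- h$beta_outcome / h$beta_exposure
    w <- (h$beta_exposure / h$se_outcome)^2
    oracle <- sum(w * ratios) / sum(w)
    expect_equal(mr_ivw(h, model = "fixed")$b, oracle, tolerance = 1e-12)
  }
})

test_that("Egger regression recovers an exact affine relationship", {
  bx <- c(0.1, 0.2, 0.3, 0.4, 0.5)
  h <- make_h(bx = bx, by = 0.02 + 0.3 * bx, sy = rep(0.1, 5))
  fit <- mr_egger(h)
  expect_equal(fit$slope$b, 0.3, tolerance = 1e-10)
  expect_equal(fit$intercept, 0.02, tolerance = 1e-10)
  expect_error(mr_egger(make_h(1:2, 1:2, c(0.1, 0.1))), "3 instruments")
})

test_that("Egger pre-orientation makes the fit allele-orientation invariant", {
  set.seed(7)
  bx <- rnorm(10, 0, 0.3)
  h <- make_h(bx = bx, by = 0.3 * bx + rnorm(10, 0, 0.05),
              sy = rep(0.05, 10))
  h_flip <- h
  h_flip$beta_exposure <- -h$beta_exposure
  h_flip$beta_outcome <- -h$beta_outcome
  expect_equal(mr_egger(h)$slope$b, mr_egger(h_flip)$slope$b)
  expect_equal(mr_egger(h)$intercept, mr_egger(h_flip)$intercept)
})

test_that("Egger intercept estimates directional pleiotropy in the noiseless limit", {
  # exactly by = alpha + theta * bx with varied instrument strengths
  bx <- seq(0.05, 0.6, length.out = 8)
  h <- make_h(bx = bx, by = 0.02 + 0.25 * bx, sy = rep(0.08, 8))
  fit <- mr_egger(h)
  expect_equal(fit$intercept, 0.02, tolerance = 1e-9)
  expect_equal(fit$slope$b, 0.25, tolerance = 1e-9)
})

test_that("weighted median interpolates the half-weight crossing", {
  # ratios {0, 1, 2} with equal weights -> 1
  h <- make_h(bx = c(1, 1, 1), by = c(0, 1, 2), sy = c(0.1, 0.1, 0.1))
  expect_equal(mr_weighted_median(h, n_boot = 10, seed = 1)$b, 1)

  # all ratios equal r -> r regardless of weights
  h2 <- make_h(bx = c(1, 2, 5), by = 0.4 * c(1, 2, 5),
               sy = c(0.3, 0.1, 0.2))
  expect_equal(mr_weighted_median(h2, n_boot = 10, seed = 1)$b, 0.4)

  expect_error(mr_weighted_median(make_h(c(0, 1, 1), c(1, 1, 1),
                                         c(0.1, 0.1, 0.1)), 10, 1),
               "rs|snp")
})

test_that("weighted median resists a minority outlier where IVW does not", {
  res <- t(vapply(1:50, function(i) {
    h <- sim_h(m_snps = 30, theta = 0.1, gamma_sd = 0.1, seed = 400 + i)
    # one wild pleiotropic instrument
    h$beta_outcome[1] <- h$beta_outcome[1] + 0.05
    c(mr_ivw(h, model = "fixed")$b,
      mr_weighted_median(h, n_boot = 2, seed = i)$b)
  }, numeric(2)))
  expect_lt(mean(abs(res[, 2] - 0.1)), mean(abs(res[, 1] - 0.1)))
  expect_lt(mean(abs(res[, 2] - 0.1)), 0.02)
})

test_that("weighted mode tracks the dominant cluster", {
  h <- make_h(bx = rep(1, 4), by = c(1, 1, 1, 5), sy = rep(0.1, 4))
  expect_equal(mr_weighted_mode(h, n_boot = 10, seed = 1)$b, 1,
               tolerance = 0.05)

  # identical ratios collapse to that ratio
  h2 <- make_h(bx = c(1, 2, 4), by = 0.7 * c(1, 2, 4), sy = rep(0.1, 3))
  expect_equal(mr_weighted_mode(h2, n_boot = 10, seed = 1)$b, 0.7)

  # permutation invariance
  h3 <- make_h(bx = c(1, 2, 1, 3), by = c(0.2, 0.5, 0.3, 0.9),
               sy = rep(0.1, 4))
  perm <- h3[c(3, 1, 4, 2), ]
  class(perm) <- class(h3)
  expect_equal(mr_weighted_mode(h3, n_boot = 2, seed = 1)$b,
               mr_weighted_mode(perm, n_boot = 2, seed = 1)$b)
})

test_that("bootstrap standard errors are seeded and reproducible", {
  h <- sim_h(m_snps = 20, theta = 0.1, seed = 3)
  a <- mr_weighted_median(h, n_boot = 200, seed = 77)
  b <- mr_weighted_median(h, n_boot = 200, seed = 77)
  expect_identical(a$se, b$se)
  c_ <- mr_weighted_median(h, n_boot = 200, seed = 78)
  expect_false(identical(a$se, c_$se))
})

test_that("odds-ratio conversion matches independently reported values", {
  expect_equal(to_or(-0.216673334, 0.068095147)$or_, 0.805192956,
               tolerance = 1e-8)
  ci <- to_or(0.230998983, 0.064346766)
  expect_equal(round(ci$ci_low, 3), 1.111)
  expect_equal(round(ci$ci_high, 3), 1.429)
  null <- to_or(0, 0.1)
  expect_equal(null$or_, 1)
  expect_equal(null$ci_low * null$ci_high, 1, tolerance = 1e-12)
})

test_that("normal-reference p-values match independently reported values", {
  expect_equal(p_from_z(-0.13603266, 0.041009329), 0.000909522,
               tolerance = 1e-5)
  expect_equal(p_from_z(0.132249905, 0.029355991), 6.64e-06,
               tolerance = 1e-2)
  expect_equal(p_from_z(0, 0.1), 1)
})

test_that("estimators are scale-equivariant in the exposure units", {
  h <- sim_h(m_snps = 20, theta = 0.1, seed = 15)
  h2 <- h
  h2$beta_exposure <- 2 * h$beta_exposure
  h2$se_exposure <- 2 * h$se_exposure
  expect_equal(mr_ivw(h2, model = "fixed")$b,
               mr_ivw(h, model = "fixed")$b / 2)
  expect_equal(mr_egger(h2)$slope$b, mr_egger(h)$slope$b / 2)
  expect_equal(mr_weighted_median(h2, n_boot = 2, seed = 1)$b,
               mr_weighted_median(h, n_boot = 2, seed = 1)$b / 2)
  expect_equal(mr_weighted_mode(h2, n_boot = 2, seed = 1)$b,
               mr_weighted_mode(h, n_boot = 2, seed = 1)$b / 2,
               tolerance = 1e-10)
})

test_that("exp/log round trip preserves the estimate", {
  b <- -0.137; se <- 0.04
  expect_equal(log(to_or(b, se)$or_), b)
})
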