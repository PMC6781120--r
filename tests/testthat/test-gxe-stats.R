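icf_block <- matrix(c(92.0, -0.849, -0.849, 0.015), 2, 2)

test_that("genetic variance along the gradient follows the quadratic form", {
  g <- matrix(c(1, -0.5, -0.5, 0.25), 2, 2)
  expect_equal(genetic_variance_at(0, g), 1)
  expect_equal(genetic_variance_at(2, g), 0)       # PSD boundary
  ## reference fertility components at f = 10
  expect_equal(genetic_variance_at(10, icf_block), 76.52)
  ## vectorised and nonnegative for a PSD block
  f <- seq(-3, 3, by = 0.5)
  expect_true(all(genetic_variance_at(f, g) >= 0))
})

test_that("heritability uses the weighted residual and excludes herd-year", {
  h <- heritability_at(0, w = 1, icf_block, sigma2_pe = 53.3,
                       sigma2_e = 728.1)
  expect_equal(h, 92.0 / (92.0 + 53.3 + 728.1), tolerance = 1e-12)
  expect_equal(round(h, 4), 0.1053)
  ## halving the weight doubles the effective residual, decreasing h2
  h_half <- heritability_at(0, w = 0.5, icf_block, sigma2_pe = 53.3,
                            sigma2_e = 728.1)
  expect_lt(h_half, h)
  ## no slope variance and unit weights: h2 constant in f
  g0 <- matrix(c(1, 0, 0, 0), 2, 2)
  hs <- heritability_at(c(-2, 0, 2), w = 1, g0, sigma2_pe = 0.3,
                        sigma2_e = 1)
  expect_equal(hs, rep(hs[1], 3))
  ## the jump at a group boundary is exactly the weight-ratio effect
  va <- genetic_variance_at(1, icf_block)
  h1 <- heritability_at(1, 1.0, icf_block, 53.3, 728.1)
  h2 <- heritability_at(1, 0.8, icf_block, 53.3, 728.1)
  expect_equal(h2, va / (va + 53.3 + 728.1 / 0.8), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(h1, h2)))
})

test_that("genetic correlations between gradients behave like the model", {
  g <- matrix(c(1, 0, 0, 1), 2, 2)
  expect_equal(genetic_correlation(0.7, 0.7, g), 1)
  expect_equal(genetic_correlation(0, 1, g), 1 / sqrt(2))
  ## no slope variance: unit correlation everywhere
  g0 <- matrix(c(1, 0, 0, 0), 2, 2)
  expect_equal(genetic_correlation(-2, 2, g0), 1)
  ## Monte-Carlo oracle: correlation of (a0 + a1 f1, a0 + a1 f2)
  set.seed(30)
  S <- matrix(c(1, -0.3, -0.3, 0.2), 2, 2)
  ab <- matrix(rnorm(8e6), ncol = 2) %*% chol(S)
  f1 <- -1.5; f2 <- 2
  mc <- cor(ab[, 1] + ab[, 2] * f1, ab[, 1] + ab[, 2] * f2)
  expect_lt(abs(genetic_correlation(f1, f2, S) - mc), 1.5e-3)
})

test_that("intercept-slope correlations reproduce the reference values", {
  expect_equal(round(intercept_slope_correlation(icf_block), 2), -0.72)
  ifl <- matrix(c(48.0, -0.621, -0.621, 0.052), 2, 2)
  expect_lt(abs(intercept_slope_correlation(ifl) - (-0.395)), 0.005)
  g <- matrix(c(1, 0, 0, 0.5), 2, 2)
  expect_equal(intercept_slope_correlation(g), 0)
  expect_error(intercept_slope_correlation(matrix(c(0, 0, 0, 1), 2, 2)),
               "zero")
})

test_that("the mixture chi-square LRT is calibrated at its reference points", {
  expect_equal(lrt_rnm_vs_rm(0, 0)$p_value, 1)
  ## D = 5: frozen mixture tail value
  expect_equal(lrt_rnm_vs_rm(-2.5, 0)$D, 5)
  ## 0.5 exp(-2.5) + 0.5 P[chisq_1 >= 5] = 0.0537161
  expect_equal(lrt_rnm_vs_rm(-2.5, 0)$p_value, 0.0537161, tolerance = 1e-5)
  ## strictly decreasing in D
  D <- seq(0, 10, by = 0.5)
  p <- vapply(D, function(d) lrt_rnm_vs_rm(0, d / 2)$p_value, numeric(1))
  expect_true(all(diff(p) < 0))
  ## numerically negative D clips to zero with a warning
  expect_warning(out <- lrt_rnm_vs_rm(1, 0.5), "clipping")
  expect_equal(out$D, 0)
})

test_that("gradient quantiles are record-weighted", {
  f <- c("1" = -1, "2" = 0, "3" = 1)
  ## herd 3 has most records: high quantiles sit on its value
  herds <- rep(c(1, 2, 3), c(10, 10, 80))
  q <- quantile_eg_values(f, herds, c(5, 50, 95))
  expect_equal(unname(q["q95"]), 1)
  expect_lt(q["q5"], 0)
  ## all herds equal: all quantiles equal and correlations are one
  feq <- c("1" = 0.4, "2" = 0.4)
  qe <- quantile_eg_values(feq, rep(c(1, 2), 10), c(1, 99))
  expect_equal(unname(qe["q1"]), unname(qe["q99"]))
  g <- matrix(c(1, -0.3, -0.3, 0.2), 2, 2)
  expect_equal(genetic_correlation(qe["q1"], qe["q99"], g), 1,
               ignore_attr = TRUE)
  expect_error(quantile_eg_values(f, herds, c(0, 50)), "between 0 and 100")
})

test_that("wider quantile gaps give lower genetic correlations", {
  set.seed(31)
  f <- setNames(rnorm(200), 1:200)
  herds <- sample(1:200, 5000, TRUE)
  q <- quantile_eg_values(f, herds)
  g <- matrix(c(1, -0.3, -0.3, 0.5), 2, 2)   # strong G x E
  r_wide <- genetic_correlation(q["q1"], q["q99"], g)
  r_narrow <- genetic_correlation(q["q20"], q["q80"], g)
  expect_lt(r_wide, r_narrow)
})

test_that("the gradient grid spans mean +/- 2.5 SD with group weights", {
  fit <- small_fit()
  grid <- eg_grid(fit$s1$f, n = 41)
  expect_equal(min(grid$normalized), -2.5)
  expect_equal(max(grid$normalized), 2.5)
  expect_true(all(grid$w == 1))
  gs <- gxe_summary(fit$s3, fit$data)
  expect_true(all(abs(gs$correlations$correlation) <= 1))
  expect_gte(gs$lrt$D, 0)
})
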