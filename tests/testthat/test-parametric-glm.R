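test_that("gamma HRF has the documented shape/scale and unit sum", {
  h <- gamma_hrf(tr = 0.5)
  expect_equal(h$shape, 4)       # mean 6 s, sd 3 s -> shape mean^2/sd^2
  expect_equal(h$scale, 1.5)     # sd^2/mean
  expect_equal(sum(h$weights), 1)
  expect_true(all(h$weights >= 0))
  # mode of a gamma(4, 1.5) is (shape-1)*scale = 4.5 s
  t <- seq(0, 30, by = 0.5)
  expect_equal(t[which.max(h$weights)], 4.5, tolerance = 0.5)
  expect_error(gamma_hrf(0), "positive")
  expect_error(gamma_hrf(1, mean_lag_s = -1), "positive")
})

test_that("convolution is causal and preserves the plateau", {
  tr <- 1
  h <- gamma_hrf(tr)
  box <- sampled_series(c(rep(0, 40), rep(1, 80)), tr = tr)
  conv <- convolve_regressor(box, h)
  expect_equal(length(conv), length(box))
  # causal: nothing before the step
  expect_equal(conv$values[1:40], rep(0, 40))
  # unit-sum kernel: long plateau converges to 1
  expect_equal(conv$values[110:120], rep(1, 11), tolerance = 1e-6)
  # monotone non-decreasing response to a step
  expect_true(all(diff(conv$values) >= -1e-12))

  # mismatched grids are refused
  expect_error(convolve_regressor(box, gamma_hrf(2)), "different sampling")
})

test_that("glm_cope recovers a planted amplitude exactly without noise", {
  tr <- 1.55
  h <- gamma_hrf(tr)
  box <- sampled_series(rep(c(0, 1), each = 100), tr = tr)
  reg <- convolve_regressor(box, h)
  y <- sampled_series(500 + 12.5 * reg$values, tr = tr)
  g <- glm_cope(y, box, h)
  expect_equal(g$cope, 12.5, tolerance = 1e-9)
  expect_equal(g$intercept, 500, tolerance = 1e-8)
  expect_equal(max(abs(g$residuals)), 0, tolerance = 1e-8)

  # linearity in the series
  y2 <- sampled_series(500 + 25 * reg$values, tr = tr)
  expect_equal(glm_cope(y2, box, h)$cope, 25, tolerance = 1e-8)

  # percent-per-mmHg normalization algebra
  g3 <- glm_cope(y, box, h, delta_petco2 = 10, baseline_mean = 500)
  expect_equal(g3$pct_equivalent, 12.5 / 500 * 100 / 10)

  # without an HRF the raw all-ones boxcar is a constant regressor
  expect_error(glm_cope(y, sampled_series(rep(1, 200), tr), hrf = NULL),
               "constant regressor")
  expect_error(glm_cope(y, sampled_series(rep(c(0, 1), 10), tr), h),
               "lengths differ")
})

test_that("glm_cope equals the normal-equations oracle on noisy data", {
  withr::with_seed(77, {
    tr <- 2
    h <- gamma_hrf(tr)
    box <- sampled_series(rep(c(0, 1, 0, 1), each = 60), tr = tr)
    reg <- convolve_regressor(box, h)
    for (i in 1:10) {
      y <- 300 + 8 * reg$values + rnorm(length(reg), 0, 5)
      g <- glm_cope(sampled_series(y, tr), box, h)
      beta <- normal_equations(cbind(1, reg$values), y)
      expect_equal(g$intercept, unname(beta[1]), tolerance = 1e-8)
      expect_equal(g$cope, unname(beta[2]), tolerance = 1e-8)
    }
  })
})

test_that("null responses give a mean COPE near zero", {
  withr::with_seed(42, {
    tr <- 1.55
    h <- gamma_hrf(tr)
    box <- sampled_series(rep(c(0, 1), each = 120), tr = tr)
    copes <- replicate(200, {
      y <- sampled_series(rnorm(240, 1000, 5), tr = tr)
      glm_cope(y, box, h)$cope
    })
    expect_lt(abs(mean(copes)), 3 * sd(copes) / sqrt(200))
  })
})

test_that("aic_ols follows its closed-form algebra", {
  # n = 100, RSS = 100 -> 100*log(1) + 2*2 = 4
  r <- rep(1, 100)
  expect_equal(aic_ols(r, 2), 4)

  # halving every residual changes AIC by n*log(1/4) = -n*log(4)
  withr::with_seed(8, {
    r2 <- rnorm(60)
    expect_equal(aic_ols(r2 / 2, 3) - aic_ols(r2, 3), 60 * log(1 / 4))
  })

  # extra parameters cost exactly 2 each
  expect_equal(aic_ols(r, 5) - aic_ols(r, 2), 6)

  expect_error(aic_ols(rep(0, 50), 2), "zero residual")
  expect_error(aic_ols(rnorm(3), 3), "more residuals")
})

test_that("shared AIC convention gives the same differences as the full constant", {
  # differences between models are convention-free: dropping the Gaussian
  # constant must not change any AIC difference
  withr::with_seed(19, {
    rA <- rnorm(80, 0, 2)
    rB <- rnorm(80, 0, 3)
    d_pkg <- aic_ols(rA, 2) - aic_ols(rB, 2)
    d_full <- aic_full_constant(rA, 2) - aic_full_constant(rB, 2)
    expect_equal(d_pkg, d_full, tolerance = 1e-10)
  })
})

test_that("aic_sen scores residuals about the Sen line", {
  withr::with_seed(55, {
    v <- 100 + 0.5 * (0:49) + rnorm(50, 0, 1)
    slope <- sens_slope(v)
    b0 <- sen_intercept(v, slope)
    manual <- aic_ols(v - (b0 + slope * (0:49)), 2)
    expect_equal(aic_sen(v), manual)
    expect_equal(aic_sen(sampled_series(v, tr = 2)), manual)  # tr-agnostic
  })
  # exact line -> zero residuals -> degenerate
  expect_error(aic_sen(2 * (0:20)), "zero residual")
})

test_that("compare_models prefers the generating model without noise", {
  fast <- simulate_epoch("fast", noise_sd = 10, seed = 5)
  slow <- simulate_epoch("slow", noise_sd = 10, seed = 5)
  cf <- compare_models(fast)
  cs <- compare_models(slow)
  expect_lt(cf$aic_parametric, cf$aic_nonparametric)
  expect_lt(cs$aic_nonparametric, cs$aic_parametric)
  expect_equal(cf$shape, "fast")
  expect_equal(cf$n, length(fast$series))

  # an exactly linear series makes the Sen fit degenerate: -Inf sentinel
  line <- sampled_series(100 + 2 * (0:99), tr = 1)
  expect_equal(compare_models(list(series = line, onset_s = 50))$aic_nonparametric,
               -Inf)
})
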