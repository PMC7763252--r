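test_that("AGO reproduces the published cumulative series and inverts exactly", {
  x0 <- comprehensive_series()
  expect_equal(ago(x0),
               c(0.1893, 0.4798, 0.8303, 1.4071, 2.1271, 2.9045, 3.7092,
                 4.5863),
               tolerance = 1e-12)
  expect_equal(ago(5), 5)
  set.seed(11)
  for (i in 1:20) {
    x <- runif(sample(4:15, 1), 0.01, 10)
    expect_equal(iago(ago(x)), x, tolerance = 1e-12)
  }
  expect_error(ago(numeric(0)), "empty")
})

test_that("mean sequence is the adjacent-pair mean", {
  x1 <- ago(comprehensive_series())
  z <- mean_sequence(x1)
  expect_length(z, 7)
  expect_equal(z[1], 0.33455)          # printed design-matrix entry -0.3346
  expect_equal(round(-z[1], 4), -0.3346)
  expect_equal(mean_sequence(c(3, 3)), 3)
  expect_equal(mean_sequence(c(1, 3)), 2)
  expect_error(mean_sequence(1), "at least 2")
})

test_that("least squares recovers the published worked-example parameters", {
  fit <- gm11(comprehensive_series())
  expect_equal(fit$a, -0.150207, tolerance = 5e-5)
  expect_equal(fit$b, 0.33103771, tolerance = 5e-5)
  expect_equal(fit$c1, 2.3931768, tolerance = 5e-4)
  expect_equal(fit$c0, -2.2038768, tolerance = 5e-4)
})

test_that("normal equations agree with the simple-regression closed form", {
  # the grey difference equation x0[k] = -a z[k] + b is a simple regression
  # of x0[2..n] on z; slope = cov(z, x)/var(z), so a = -slope
  for (x in list(comprehensive_series(),
                 generate_grey_series(-0.08, 0.5, 0.3, 9) * (1 + 0.01 * 1:9))) {
    fit <- gm11(x)
    z <- mean_sequence(ago(x))
    y <- x[-1]
    slope <- stats::cov(z, y) / stats::var(z)
    expect_equal(fit$a, -slope, tolerance = 1e-10)
    expect_equal(fit$b, mean(y) - slope * mean(z), tolerance = 1e-10)
  }
})

test_that("difference restoration reproduces the published fitted series", {
  fit <- gm11(comprehensive_series())
  expect_equal(fit$fitted,
               c(0.1893, 0.3879, 0.4507, 0.5238, 0.6087, 0.7073, 0.8220,
                 0.9552),
               tolerance = 5e-4)
  expect_equal(fit$fitted[1], fit$x0[1])  # boundary condition
})

test_that("derivative restoration carries the published forecast multiplier", {
  fit <- gm11(comprehensive_series())
  expect_equal(-fit$a * fit$c1, 0.359472, tolerance = 5e-6)
  d <- restore_fitted(fit, "derivative")
  expect_equal(d[1], fit$x0[1])
  expect_equal(d[-1], -fit$a * fit$c1 * exp(-fit$a * (1:7)), tolerance = 1e-12)
})

test_that("a zero-residual grey series is recovered: parameters exactly,
           fitted values to the discretization bound", {
  x <- generate_grey_series(-0.05, 0.3, 0.2, 8)
  fit <- gm11(x)
  expect_equal(fit$a, -0.05, tolerance = 1e-8)
  expect_equal(fit$b, 0.3, tolerance = 1e-8)
  # difference restoration evaluates the continuous-time (whitened) solution,
  # which matches the discrete difference equation to c1 * a^3/12 per step
  # (~ b * a^2/12): exact in the small-a limit, analytically bounded otherwise
  xs <- generate_grey_series(-1e-4, 0.3, 0.3, 8)
  fs <- gm11(xs)
  expect_equal(restore_fitted(fs, "difference")[-1], xs[-1],
               tolerance = 1e-8)
  bound <- length(x) * fit$c1 * abs(fit$a)^3
  expect_lt(max(abs(restore_fitted(fit, "difference")[-1] - x[-1])), bound)
  # the two restorations differ by the exact factor a / (e^a - 1) beyond k=1
  for (f in list(fit, fs))
    expect_equal(restore_fitted(f, "derivative")[-1],
                 restore_fitted(f, "difference")[-1] * f$a / (exp(f$a) - 1),
                 tolerance = 1e-12)
})

test_that("forecasts continue the series and grow when a < 0", {
  fit <- gm11(comprehensive_series(), years = 2011:2018)
  expect_equal(nrow(predict(fit, 0)), 0)
  fc <- predict(fit, 3)
  expect_equal(fc$year, 2019:2021)
  # direct evaluation of the prediction formula at k = 8 (the 2019 value)
  expect_equal(fc$predicted[1], -fit$a * fit$c1 * exp(-fit$a * 8),
               tolerance = 1e-12)
  expect_true(all(diff(fc$predicted) > 0))
  expect_error(predict(fit, -1), "non-negative")
})

test_that("the fit is scale-equivariant", {
  x <- comprehensive_series()
  fit <- gm11(x)
  for (s in c(0.2, 3, 117)) {
    fs <- gm11(s * x)
    expect_equal(fs$a, fit$a, tolerance = 1e-10)
    expect_equal(fs$b, s * fit$b, tolerance = 1e-10 * s)
    expect_equal(fs$fitted, s * fit$fitted, tolerance = 1e-10 * s)
  }
})

test_that("invalid series are rejected", {
  expect_error(gm11(c(1, 2, 3)), "at least 4")
  expect_error(gm11(c(1, -2, 3, 4)), "positive")
  expect_error(gm11(c(1, NA, 3, 4)), "non-finite")
  expect_error(restore_fitted(gm11(comprehensive_series()), "spline"))
})
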