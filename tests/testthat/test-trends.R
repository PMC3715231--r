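test_that("ols_fit recovers exact lines and flags degenerate designs", {
  f <- ols_fit(1:6, 2 * (1:6) + 1)
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  expect_equal(f$r2, 1)
  expect_error(ols_fit(rep(2, 5), 1:5), "degenerate")
  expect_error(ols_fit(1:3, 1:2), "length")
  # orthogonal residual construction: zero slope, zero r2
  x <- c(-2, -1, 0, 1, 2)
  y <- c(1, -1, 0, -1, 1)          # even function of x, uncorrelated
  f0 <- ols_fit(x, y)
  expect_equal(f0$slope, 0)
  expect_equal(f0$r2, 0)
})

test_that("ols_fit equals the closed-form normal-equation oracle", {
  set.seed(43)
  for (i in 1:25) {
    n <- sample(3:40, 1)
    x <- rnorm(n, sd = runif(1, 0.5, 20))
    y <- runif(1, -3, 3) * x + rnorm(1, 0, 5) + rnorm(n)
    f <- ols_fit(x, y)
    o <- ols_normal_equations(x, y)
    expect_equal(f$slope, unname(o["slope"]), tolerance = 1e-10)
    expect_equal(f$intercept, unname(o["intercept"]), tolerance = 1e-10)
    # r2 equals squared sample correlation for simple regression
    expect_equal(f$r2, cor(x, y)^2, tolerance = 1e-10)
    # invariance under affine rescaling of x (slope transforms as 1/a)
    a <- runif(1, 0.1, 5); b <- rnorm(1)
    f2 <- ols_fit(a * x + b, y)
    expect_equal(f2$slope, f$slope / a, tolerance = 1e-8)
    expect_equal(f2$r2, f$r2, tolerance = 1e-10)
  }
})

test_that("log-threshold vs MW regression recovers a generating slope", {
  set.seed(47)
  mw <- runif(40, 40, 180)
  reg <- validate_registry(data.frame(
    name = sprintf("c%02d", 1:40), group = "ester", mw = mw,
    thresholds = sprintf("%.6g@sim", 10^(-0.02 * mw + 2 + rnorm(40, 0, 0.1)))))
  fit <- threshold_mw_regression(reg, "max")$fits$pooled
  expect_lt(abs(fit$slope - (-0.02)) / 0.02, 0.15)
  expect_lt(fit$p_value, 0.05)
})

test_that("equal thresholds give a zero slope; generated inverse trends are negative for every statistic", {
  reg_flat <- validate_registry(data.frame(
    name = c("a", "b", "c", "d"), group = "ester",
    mw = c(60, 90, 120, 150), thresholds = "25@x"))
  expect_equal(threshold_mw_regression(reg_flat)$fits$pooled$slope, 0)

  set.seed(53)
  sc <- study_scenario()
  reg <- generate_registry(sc)
  for (st in c("max", "min", "geomean"))
    expect_lt(threshold_mw_regression(reg, st)$fits$pooled$slope, 0)
})

test_that("small groups are skipped with a warning in per-group fits", {
  reg <- validate_registry(data.frame(
    name = sprintf("c%d", 1:5),
    group = c(rep("ester", 3), rep("ketone", 2)),
    mw = c(60, 90, 120, 80, 110),
    thresholds = sprintf("%g@x", c(30, 12, 4, 100, 50))))
  expect_warning(res <- threshold_mw_regression(reg, scope = "per_group"),
                 "ketone")
  expect_named(res$fits, "ester")
})

test_that("intensity trends follow the closed-form decay slope", {
  days <- 0:6
  f <- intensity_trend(days, 100 * 0.5^days)
  expect_equal(f$slope, log10(0.5), tolerance = 1e-12)
  expect_equal(f$r2, 1)
  fc <- intensity_trend(days, rep(4, 7))
  expect_equal(fc$slope, 0)
  expect_error(intensity_trend(c(0, 1, 3), c(5, 0, 2)), "day")
})

test_that("the published summed-OAV sequence decays log-linearly in time", {
  f <- intensity_trend(c(0, 1, 3, 6, 9), c(12972, 6992, 2524, 196, 7.37))
  expect_lt(f$slope, 0)
  expect_gt(f$r2, 0.9)
  # agrees with the generic OLS fit of the transformed data
  g <- ols_fit(c(0, 1, 3, 6, 9), log10(c(12972, 6992, 2524, 196, 7.37)))
  expect_equal(f$slope, g$slope)
  expect_equal(f$r2, g$r2)
})

test_that("OAV / dilution-to-threshold correlation recovers power laws", {
  s <- data.frame(day = c(0, 1, 3, 6, 9),
                  sum_oav = c(12972, 6992, 2524, 196, 7.37))
  ident <- oav_dt_correlation(s, data.frame(day = s$day, dt_ratio = s$sum_oav))
  expect_equal(ident$slope, 1, tolerance = 1e-12)
  expect_equal(ident$r2, 1)
  pl <- oav_dt_correlation(s, data.frame(day = s$day,
                                         dt_ratio = 3 * s$sum_oav^0.43))
  expect_equal(pl$slope, 0.43, tolerance = 1e-10)
  expect_equal(pl$r2, 1)
  set.seed(59)
  noisy <- oav_dt_correlation(s, data.frame(
    day = s$day, dt_ratio = 3 * s$sum_oav^0.43 * rlnorm(5, 0, 0.05)))
  expect_lt(abs(noisy$slope - 0.43) / 0.43, 0.10)
  expect_error(oav_dt_correlation(s, data.frame(day = c(0, 1, 3, 6, 10),
                                                dt_ratio = 1:5)),
               "unpaired")
})
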