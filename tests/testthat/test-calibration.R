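test_that("calibration matches closed-form least squares on the standards", {
  # collinear standards: exact line
  cv <- fit_calibration(c(0, 100, 300), c(-50, 0, 100))
  expect_equal(cv$slope, 0.5, tolerance = 1e-12)
  expect_equal(cv$intercept, -50, tolerance = 1e-12)
  expect_equal(cv$r_squared, 1, tolerance = 1e-12)
  expect_equal(cv$intercept_se, 0, tolerance = 1e-9)
  expect_false(cv$degenerate)

  # non-collinear standards: OLS, checked against the closed form
  cv2 <- fit_calibration(c(0, 100, 300), c(-60, 0, 90))
  oracle <- ols_closed_form(c(0, 100, 300), c(-60, 0, 90))
  expect_equal(cv2$slope, oracle$slope, tolerance = 1e-12)          # 0.49286
  expect_equal(cv2$intercept, oracle$intercept, tolerance = 1e-12)  # -55.714
  expect_equal(cv2$intercept_se, oracle$intercept_se, tolerance = 1e-9)
  expect_equal(cv2$slope, 0.4928571, tolerance = 1e-6)
  expect_equal(cv2$intercept, -55.71429, tolerance = 1e-6)

  # randomized triples against the closed form
  set.seed(101)
  for (i in 1:50) {
    y <- rnorm(3, c(-120, 0, 120), 25)
    cv3 <- fit_calibration(c(0, 100, 300), y)
    o <- ols_closed_form(c(0, 100, 300), y)
    expect_equal(cv3$slope, o$slope, tolerance = 1e-12)
    expect_equal(cv3$intercept, o$intercept, tolerance = 1e-12)
    expect_equal(cv3$intercept_se, o$intercept_se, tolerance = 1e-9)
  }
})

test_that("flat standard response flags the card degenerate instead of erroring", {
  cv <- fit_calibration(c(0, 100, 300), c(12, 12, 12))
  expect_true(cv$degenerate)
  expect_equal(cv$slope, 0)
  expect_error(quantify(10, cv), "degenerate")
})

test_that("calibration rejects malformed standards", {
  expect_error(fit_calibration(c(0, 100, 200), c(-1, 0, 1)), "0, 100 and 300")
  expect_error(fit_calibration(c(0, 100, 300), c(-1, NA, 1)), "finite")
  expect_error(fit_calibration(c(0, 100), c(-1, 0)), "three")
})

test_that("quantify inverts the calibration line and flags out-of-range values", {
  cv <- fit_calibration(c(0, 100, 300), c(-50, 0, 100))
  expect_equal(quantify(25, cv)$estimate, 150)
  expect_equal(quantify(cv$intercept, cv)$estimate, 0)
  q <- quantify(-60, cv)
  expect_equal(q$estimate, -20)
  expect_true(q$below_range_negative)
  q2 <- quantify(130, cv)
  expect_equal(q2$estimate, 360)
  expect_true(q2$above_range_extrapolated)

  # inversion identity over random curves and concentrations
  set.seed(7)
  for (i in 1:25) {
    y <- rnorm(3, c(-120, 0, 120), 20)
    curve <- fit_calibration(c(0, 100, 300), y)
    conc <- runif(5, -50, 450)
    back <- quantify(curve$slope * conc + curve$intercept, curve)$estimate
    expect_equal(back, conc, tolerance = 1e-9)
  }

  # monotone: positive slope means higher score -> higher concentration
  s <- seq(-100, 150, by = 10)
  expect_true(all(diff(quantify(s, cv)$estimate) > 0))
})

test_that("collinear standards are recovered exactly by inversion", {
  cv <- fit_calibration(c(0, 100, 300), c(-50, 0, 100))
  for (conc in c(0, 100, 300)) {
    s <- cv$slope * conc + cv$intercept
    expect_equal(quantify(s, cv)$estimate, conc, tolerance = 1e-12)
  }
})

test_that("replicate pooling averages and propagates flags", {
  expect_equal(pool_replicates(c(140, 150, 160))$pooled_estimate, 150)
  expect_equal(pool_replicates(150)$pooled_estimate, 150)
  p <- pool_replicates(c(100, 100, 400))
  expect_equal(p$pooled_estimate, 200)
  expect_true(p$above_range_extrapolated)   # propagated from the 400 replicate
  expect_equal(pool_replicates(c(100, 150, 350), method = "median")$pooled_estimate,
               150)
  expect_error(pool_replicates(numeric(0)), "no replicates")
  expect_error(pool_replicates(1:4), "at most three")
})
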