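test_that("noiseless linear data are recovered exactly", {
  x <- c(1, 10, 100)
  cv <- fit_calibration(x, 6564.29 * x - 354.886, analyte = "G")
  expect_equal(cv$slope_a, 6564.29, tolerance = 1e-9)
  expect_equal(cv$intercept_b, -354.886, tolerance = 1e-9)
  expect_equal(cv$r_squared, 1, tolerance = 1e-9)
  expect_equal(unname(cv$linear_range), c(1, 100))
})

test_that("OLS matches the closed-form fit on a hand example", {
  cv <- fit_calibration(c(1, 2, 3), c(1, 2, 4))
  expect_equal(cv$slope_a, 1.5)
  expect_equal(cv$intercept_b, -2 / 3)
})

test_that("degenerate designs are rejected", {
  expect_error(fit_calibration(5, 100), "at least 2")
  expect_error(fit_calibration(c(5, 5, 5), c(1, 2, 3)), "singular")
  expect_error(fit_calibration(c(-1, 2), c(1, 2)), "> 0")
})

test_that("r-squared is invariant under positive rescaling of areas", {
  set.seed(11)
  for (i in 1:10) {
    x <- sort(runif(6, 1, 100))
    y <- 50 * x + 10 + rnorm(6, sd = 20)
    k <- runif(1, 0.01, 100)
    expect_equal(fit_calibration(x, k * y)$r_squared,
                 fit_calibration(x, y)$r_squared, tolerance = 1e-12)
  }
})

test_that("back-calculation inverts the fitted line within range", {
  cv <- fit_calibration(c(1, 10, 100), 6564.29 * c(1, 10, 100) - 354.886)
  for (conc in c(1, 5, 50, 100)) {
    q <- quantify_es(cv$slope_a * conc + cv$intercept_b, cv)
    expect_equal(q$conc, conc, tolerance = 1e-9)
    expect_equal(q$flag, "ok")
  }
})

test_that("out-of-range and negative back-calculations are flagged or censored", {
  cv <- calibration_curve(100, -50, range_low = 1, range_high = 100)
  at_intercept <- quantify_es(-50, cv)
  expect_equal(at_intercept$conc, 0)
  expect_equal(at_intercept$flag, "below_range")
  below <- quantify_es(-60, cv)   # area < intercept: negative back-calculation
  expect_true(is.na(below$conc))
  expect_equal(below$censored, "below_range")
  above <- quantify_es(100 * 200 - 50, cv)
  expect_equal(above$flag, "above_range")
  missing <- quantify_es(NA, cv)
  expect_equal(missing$censored, "missing_area")
})

test_that("LOD/LOQ interpolation reproduces the identity and hand oracles", {
  # S/N numerically equal to conc: thresholds at 3 and 10 ng/mL
  ll <- estimate_lod_loq(1:20, 1:20, injection_volume = 1000)
  expect_equal(ll$lod_ng, 3, tolerance = 1e-9)
  expect_equal(ll$loq_ng, 10, tolerance = 1e-9)

  # two-point series: S/N = 0.2 * conc is a log-log line of slope 1, so the
  # interpolated concentrations are 15 (S/N 3) and, extrapolating, 50 (S/N 10)
  expect_warning(ll2 <- estimate_lod_loq(c(10, 40), c(2, 8), injection_volume = 10),
                 "extrapolating")
  expect_equal(ll2$lod_ng, 15 * 10 / 1000, tolerance = 1e-9)
  expect_equal(ll2$loq_ng, 50 * 10 / 1000, tolerance = 1e-9)

  expect_error(estimate_lod_loq(c(1, 2, 3), c(5, 4, 6), injection_volume = 10),
               "increase strictly")
  expect_error(
    suppressWarnings(estimate_lod_loq(c(10, 40), c(0.5, 1), injection_volume = 10,
                                      extrapolate = FALSE)),
    "extrapolation disabled")
})

test_that("LOD is below LOQ and both scale with injection volume", {
  set.seed(3)
  for (i in 1:10) {
    conc <- sort(runif(6, 0.5, 200))
    snr <- 0.8 * conc^runif(1, 0.8, 1.2)
    ll1 <- suppressWarnings(estimate_lod_loq(conc, snr, injection_volume = 10))
    ll5 <- suppressWarnings(estimate_lod_loq(conc, snr, injection_volume = 50))
    expect_lt(ll1$lod_ng, ll1$loq_ng)
    expect_equal(ll5$lod_ng, 5 * ll1$lod_ng, tolerance = 1e-12)
    expect_equal(ll5$loq_ng, 5 * ll1$loq_ng, tolerance = 1e-12)
  }
})

test_that("curve tables round-trip through CSV", {
  curves <- list(G = calibration_curve(6564.29, -354.886, 0.9868, 98.68,
                                       analyte = "G", r_squared = 0.9998),
                 I = calibration_curve(11955, 391.889, 0.9276, 92.76,
                                       analyte = "I", r_squared = 0.9989))
  path <- withr::local_tempfile(fileext = ".csv")
  write_curve_table(curves, path)
  back <- read_curve_table(path)
  expect_equal(back$G$slope_a, 6564.29)
  expect_equal(back$I$intercept_b, 391.889)
  expect_equal(unname(back$G$linear_range), c(0.9868, 98.68))
})
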