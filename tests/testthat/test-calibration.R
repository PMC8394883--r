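test_that("an exact line is recovered with R^2 = 1", {
  conc <- 10^c(-12, -10, -8, -6)
  pts <- data.frame(concentration = conc,
                    response = 1 - 0.1 * log10(conc))
  m <- fit_calibration(pts, "T_parallel", 450, "linear")
  expect_equal(m$coefficients, c(1, -0.1), tolerance = 1e-12)
  expect_equal(m$r_squared, 1, tolerance = 1e-12)
  expect_equal(m$fit_range, c(-12, -6))
})

test_that("fit rejects nonpositive concentrations and short designs", {
  expect_error(fit_calibration(
    data.frame(concentration = c(0, 1e-8), response = c(1, 2)),
    "T_parallel", 450, "linear"), "positive")
  expect_error(fit_calibration(
    data.frame(concentration = 10^c(-8, -7, -6), response = 1:3),
    "T_parallel", 450, "cubic"), "at least 4 distinct")
})

test_that("OLS agrees with an independent normal-equations oracle", {
  set.seed(314)
  for (k in 1:20) {
    n <- sample(5:12, 1)
    x <- sort(runif(n, -12, -5))
    y <- runif(1, 0.5, 1.5) + runif(1, -0.2, 0.2) * x + rnorm(n, 0, 0.05)
    m <- fit_calibration(
      data.frame(concentration = 10^x, response = y),
      "T_parallel", 450, "linear")
    o <- ols_oracle(x, y, degree = 1)
    expect_equal(m$coefficients, o$coefficients, tolerance = 1e-10)
    expect_equal(m$intercept_se, o$se[1], tolerance = 1e-10)
    expect_equal(m$residual_sd, o$sigma, tolerance = 1e-10)
    mc <- fit_calibration(
      data.frame(concentration = 10^x, response = y + 0.01 * x^3),
      "T_parallel", 450, "cubic")
    oc <- ols_oracle(x, y + 0.01 * x^3, degree = 3)
    expect_equal(mc$coefficients, oc$coefficients, tolerance = 1e-8)
  }
})

test_that("3s/m LOD: oracle s, scale equivariance, and both conventions", {
  set.seed(99)
  x <- seq(-12, -9, length.out = 8)
  y <- 0.95 - 0.08 * x + rnorm(8, 0, 0.01)
  pts <- data.frame(concentration = 10^x, response = y)
  m <- fit_calibration(pts, "T_crossed", 450, "linear")
  lod_a <- limit_of_detection(m, "abscissa-domain")
  o <- ols_oracle(x, y, degree = 1)
  expect_equal(lod_a$intercept_sd_s, o$se[1], tolerance = 1e-10)
  expect_equal(lod_a$lod_concentration,
               10^(3 * o$se[1] / abs(o$coefficients[2])), tolerance = 1e-12)
  expect_identical(lod_a$convention, "abscissa-domain")
  # affine rescaling of the response leaves the abscissa-domain LOD unchanged
  for (ab in list(c(2, 0), c(2, 5), c(-3, 1), c(0.1, -0.4))) {
    pts2 <- transform(pts, response = ab[1] * response + ab[2])
    m2 <- fit_calibration(pts2, "T_crossed", 450, "linear")
    expect_equal(m2$intercept_se / abs(m2$slope),
                 m$intercept_se / abs(m$slope), tolerance = 1e-10)
    expect_equal(limit_of_detection(m2, "abscissa-domain")$lod_concentration,
                 lod_a$lod_concentration, tolerance = 1e-10)
  }
  # doubling responses doubles s and |m|
  m3 <- fit_calibration(transform(pts, response = 2 * response),
                        "T_crossed", 450, "linear")
  expect_equal(m3$intercept_se, 2 * m$intercept_se, tolerance = 1e-10)
  expect_equal(abs(m3$slope), 2 * abs(m$slope), tolerance = 1e-10)
  # signal-domain convention regresses against linear concentration
  lod_s <- limit_of_detection(m, "signal-domain")
  fit_lin <- ols_oracle(10^x, y, degree = 1)
  expect_equal(lod_s$lod_concentration,
               3 * fit_lin$se[1] / abs(fit_lin$coefficients[2]),
               tolerance = 1e-10)
  # convention is mandatory in spirit: linear form is, too
  mc <- fit_calibration(data.frame(concentration = 10^seq(-12, -5),
                                   response = seq(-12, -5)^3 * 1e-3),
                        "T_parallel", 450, "cubic")
  expect_error(limit_of_detection(mc, "abscissa-domain"), "linear-form")
})

test_that("halving the noise halves the intercept SE (Monte Carlo)", {
  x <- seq(-12, -9, length.out = 8)
  s_at <- function(sigma, seeds) {
    vapply(seeds, function(sd) {
      set.seed(sd)
      y <- 1 - 0.1 * x + rnorm(8, 0, sigma)
      fit_calibration(data.frame(concentration = 10^x, response = y),
                      "T_parallel", 450, "linear")$intercept_se
    }, numeric(1))
  }
  seeds <- 1:400
  ratio <- mean(s_at(0.01, seeds)) / mean(s_at(0.02, seeds))
  expect_equal(ratio, 0.5, tolerance = 0.05)
})

test_that("inverse prediction solves within range and guards against misuse", {
  x <- seq(-12, -5)
  pts <- data.frame(concentration = 10^x, response = 1 + 0.1 * x)
  m <- fit_calibration(pts, "T_crossed", 450, "linear")
  pred <- predict_concentration(m, 0.5)
  expect_equal(pred$log10_concentration, -5, tolerance = 1e-9)
  expect_equal(pred$concentration, 1e-5, tolerance = 1e-8)
  # a response mapping outside the fitted range is refused
  m_dec <- fit_calibration(
    data.frame(concentration = 10^x, response = 1 - 0.1 * x),
    "T_parallel", 450, "linear")
  expect_error(predict_concentration(m_dec, 0.5), "outside the fitted")
  # round-trip identity over the fit range
  set.seed(11)
  cubic_pts <- data.frame(concentration = 10^x,
                          response = 0.9 - 0.05 * x - 0.002 * x^2)
  mc <- fit_calibration(cubic_pts, "T_parallel", 450, "cubic")
  for (xx in seq(-11.5, -5.5, length.out = 7)) {
    y <- evaluate_calibration(mc, xx)
    expect_equal(predict_concentration(mc, y)$log10_concentration, xx,
                 tolerance = 1e-9)
  }
  # interval propagation is present and ordered
  y0 <- evaluate_calibration(mc, -8)
  p <- predict_concentration(mc, y0, response_sd = 0.01)
  expect_true(p$conc_lower < p$concentration && p$concentration < p$conc_upper)
})

test_that("a non-monotone cubic warns at fit time and refuses ambiguous inversion", {
  x <- seq(-12, -5)
  y <- sin(x)  # strongly non-monotone over the range
  expect_warning(
    m <- fit_calibration(data.frame(concentration = 10^x, response = y),
                         "T_parallel", 450, "cubic"),
    "not monotone")
  mid <- mean(range(evaluate_calibration(m, seq(-12, -5, length.out = 101))))
  expect_error(predict_concentration(m, mid), "multiple in-range roots")
})

test_that("the wavelength scan orders sensitivity and flags ties", {
  x <- seq(-12, -9)
  mk <- function(slope, wl) fit_calibration(
    data.frame(concentration = 10^x, response = 1 + slope * x + c(0, 1e-3, -1e-3, 0)),
    "T_crossed", wl, "linear")
  models <- list(mk(0.10, 450), mk(0.06, 600), mk(0.03, 800))
  scan <- wavelength_sensitivity_scan(models, "abscissa-domain")
  expect_equal(scan$wavelength_nm, c(450, 600, 800))
  expect_true(scan$most_sensitive[1] && !any(scan$most_sensitive[-1]))
  expect_true(all(diff(scan$abs_slope) < 0))
  # identical models at all wavelengths: tie reported, no crash
  tie <- wavelength_sensitivity_scan(list(mk(0.05, 450), mk(0.05, 800)))
  expect_true(all(tie$most_sensitive))
  expect_error(wavelength_sensitivity_scan(models[1]), ">= 2 wavelengths")
})
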