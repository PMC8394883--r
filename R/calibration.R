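#' Fit a calibration curve against log10 concentration
#'
#' Ordinary least squares of a response channel (reduced transmittance
#' `T_parallel` or `T_crossed`, or their `ratio`) on
#' \eqn{x = \log_{10}(c / (\mathrm{g/mL}))}. Two forms are supported:
#' `"linear"` (used for ratio calibrations and for the narrow linear range
#' feeding the limit of detection) and `"cubic"` (third-order polynomial,
#' which accommodates the S-shaped saturation of the dose curve over the
#' full dilution series). The goodness of fit is the plain coefficient of
#' determination \eqn{R^2 = 1 - SS_{res}/SS_{tot}} for both forms.
#'
#' True blanks (concentration 0) are inadmissible here: the blank enters
#' the analysis only through the analyte-free reference spectra of the
#' reduction step. Fits are unweighted; replicate standard deviations are
#' carried along for prediction intervals only.
#'
#' @param points Data frame with columns `concentration` (g/mL, > 0) and
#'   `response`, optionally `response_sd`.
#' @param response Channel name: `"T_parallel"`, `"T_crossed"` or `"ratio"`.
#' @param wavelength_nm Wavelength at which the responses were read, nm.
#' @param form `"linear"` or `"cubic"`.
#' @return An object of class `calibration_model`: response, wavelength,
#'   form, `coefficients` (intercept first), `fit_range` (log10
#'   concentration), `r_squared`, `n_points`, `residual_sd`,
#'   `intercept_se`, `slope` (linear form only), `monotone` flag, and the
#'   fitted `data`. A non-monotone cubic over its fit range triggers a
#'   warning at fit time (inversion would be ambiguous).
#' @export
fit_calibration <- function(points,
                            response = c("T_parallel", "T_crossed", "ratio"),
                            wavelength_nm = NA_real_,
                            form = c("linear", "cubic")) {
  response <- match.arg(response)
  form <- match.arg(form)
  stopifnot(is.data.frame(points),
            all(c("concentration", "response") %in% names(points)))
  keep <- is.finite(points$response)
  points <- points[keep, , drop = FALSE]
  if (any(points$concentration <= 0))
    stop("fit_calibration: concentrations must be positive (blanks enter via the reference spectra, not the fit)")
  x <- log10(points$concentration)
  y <- points$response
  degree <- if (form == "linear") 1L else 3L
  if (length(unique(x)) < degree + 1)
    stop(sprintf("fit_calibration: need at least %d distinct concentrations for a %s fit",
                 degree + 1, form))
  fit <- if (form == "linear") stats::lm(y ~ x)
         else stats::lm(y ~ x + I(x^2) + I(x^3))
  if (any(!is.finite(stats::coef(fit))))
    stop("fit_calibration: singular (rank-deficient) design")
  sm <- summary(fit)
  coefs <- unname(stats::coef(fit))
  fr <- range(x)
  monotone <- TRUE
  if (form == "cubic") {
    xs <- seq(fr[1], fr[2], length.out = 201)
    dy <- coefs[2] + 2 * coefs[3] * xs + 3 * coefs[4] * xs^2
    monotone <- all(dy >= 0) || all(dy <= 0)
    if (!monotone)
      warning("fit_calibration: fitted cubic is not monotone over its fit range; inverse prediction may be ambiguous")
  }
  structure(
    list(response = response, wavelength_nm = wavelength_nm, form = form,
         coefficients = coefs, fit_range = fr,
         r_squared = sm$r.squared, n_points = length(y),
         residual_sd = sm$sigma,
         intercept_se = sm$coefficients[1, 2],
         slope = if (form == "linear") coefs[2] else NA_real_,
         monotone = monotone,
         data = data.frame(x = x, y = y,
                           response_sd = if ("response_sd" %in% names(points))
                             points$response_sd else NA_real_)),
    class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("<calibration_model> %s @ %g nm, %s fit, n = %d, R^2 = %.4f\n",
              x$response, x$wavelength_nm, x$form, x$n_points, x$r_squared))
  cat("  coefficients (intercept first):",
      paste(format(x$coefficients, digits = 6), collapse = ", "), "\n")
  invisible(x)
}

#' Evaluate a calibration model at log10 concentrations
#'
#' @param model A `calibration_model`.
#' @param log10_concentration Abscissa values, log10 of g/mL.
#' @return Predicted responses.
#' @export
evaluate_calibration <- function(model, log10_concentration) {
  stopifnot(inherits(model, "calibration_model"))
  x <- log10_concentration
  drop(outer(x, seq_along(model$coefficients) - 1, `^`) %*% model$coefficients)
}

#' Limit of detection by the 3s/m rule
#'
#' \eqn{\mathrm{LOD} = 3 s / m}, where \eqn{s} is the standard deviation
#' (standard error) of the fitted y-intercept and \eqn{m} the slope of the
#' linear calibration. With a log10-concentration abscissa this ratio has
#' units of log10 concentration, so two explicit conventions are offered
#' and one must always be named:
#'
#' * `"abscissa-domain"`: \eqn{\Delta x = 3 s / |m|} in log10 units is
#'   exponentiated against a 1 g/mL anchor,
#'   \eqn{\mathrm{LOD} = 10^{3s/|m|}} g/mL. Invariant under affine
#'   rescaling of the response (both \eqn{s} and \eqn{|m|} scale alike).
#' * `"signal-domain"`: the calibration points are re-regressed against
#'   linear concentration (g/mL) over the model's range and
#'   \eqn{\mathrm{LOD} = 3 s / |m|} is taken directly in g/mL.
#'
#' @param model A linear-form `calibration_model`.
#' @param convention `"abscissa-domain"` or `"signal-domain"`; required,
#'   never defaulted silently.
#' @return An object of class `lod_result`: `lod_concentration` (g/mL),
#'   `slope_m`, `intercept_sd_s`, `regression_range` (log10 g/mL) and the
#'   echoed `convention`.
#' @export
limit_of_detection <- function(model,
                               convention = c("abscissa-domain",
                                              "signal-domain")) {
  convention <- match.arg(convention)
  stopifnot(inherits(model, "calibration_model"))
  if (model$form != "linear")
    stop("limit_of_detection: requires a linear-form calibration model")
  if (!is.finite(model$slope) || model$slope == 0)
    stop("limit_of_detection: calibration slope is zero; LOD undefined")
  if (convention == "abscissa-domain") {
    s <- model$intercept_se
    m <- model$slope
    lod <- 10^(3 * s / abs(m))
  } else {
    conc <- 10^model$data$x
    fit <- stats::lm(model$data$y ~ conc)
    sm <- summary(fit)
    s <- sm$coefficients[1, 2]
    m <- unname(stats::coef(fit)[2])
    if (!is.finite(m) || m == 0)
      stop("limit_of_detection: degenerate linear-concentration regression")
    lod <- 3 * s / abs(m)
  }
  structure(
    list(lod_concentration = lod, slope_m = m, intercept_sd_s = s,
         regression_range = model$fit_range, convention = convention,
         response = model$response, wavelength_nm = model$wavelength_nm),
    class = "lod_result")
}

#' @export
print.lod_result <- function(x, ...) {
  cat(sprintf("<lod_result> %s @ %g nm (%s): LOD = %.3g g/mL (m = %.4g, s = %.4g)\n",
              x$response, x$wavelength_nm, x$convention,
              x$lod_concentration, x$slope_m, x$intercept_sd_s))
  invisible(x)
}

#' Invert a calibration curve to predict a concentration
#'
#' Solves the fitted polynomial for the abscissa within the model's fit
#' range and exponentiates the unique in-range root to g/mL. A cubic with
#' several in-range roots fails loudly (reporting all roots) rather than
#' guessing, and a response outside the fitted response range is rejected.
#' When a response standard deviation is supplied, a first-order interval
#' \eqn{\Delta x = \sigma_y / |dy/dx|} at the solution is propagated to a
#' concentration interval.
#'
#' @param model A `calibration_model`.
#' @param response_value Observed response.
#' @param response_sd Optional response standard deviation.
#' @return List with `concentration` (g/mL), `log10_concentration`, and,
#'   when `response_sd` is given, `conc_lower`/`conc_upper`.
#' @export
predict_concentration <- function(model, response_value, response_sd = NULL) {
  stopifnot(inherits(model, "calibration_model"),
            is.finite(response_value))
  yr <- range(evaluate_calibration(
    model, seq(model$fit_range[1], model$fit_range[2], length.out = 401)))
  tol <- 1e-9 * max(1, abs(yr))
  if (response_value < yr[1] - tol[1] || response_value > yr[2] + tol[1])
    stop(sprintf("predict_concentration: response %.6g outside the fitted response range [%.6g, %.6g]",
                 response_value, yr[1], yr[2]))
  cf <- model$coefficients
  cf[1] <- cf[1] - response_value
  roots <- polyroot(cf)
  real <- Re(roots)[abs(Im(roots)) < 1e-8 * (1 + abs(Re(roots)))]
  rtol <- 1e-9 * max(1, diff(model$fit_range))
  inr <- real[real >= model$fit_range[1] - rtol & real <= model$fit_range[2] + rtol]
  inr <- unique(signif(inr, 12))
  if (length(inr) == 0)
    stop("predict_concentration: no root within the calibration's fit range")
  if (length(inr) > 1)
    stop(sprintf("predict_concentration: calibration is non-monotone; multiple in-range roots: %s",
                 paste(format(inr, digits = 8), collapse = ", ")))
  x <- inr
  out <- list(concentration = 10^x, log10_concentration = x)
  if (!is.null(response_sd) && is.finite(response_sd)) {
    dydx <- sum(model$coefficients[-1] *
                  seq_along(model$coefficients[-1]) *
                  x^(seq_along(model$coefficients[-1]) - 1))
    dx <- abs(response_sd / dydx)
    out$conc_lower <- 10^(x - dx)
    out$conc_upper <- 10^(x + dx)
  }
  out
}

#' Sensitivity and LOD across wavelengths
#'
#' Tabulates slope magnitude and limit of detection for a set of
#' linear-form calibration models fitted at different wavelengths, and
#' flags the most sensitive wavelength (largest `|slope|`; ties all
#' flagged). Sensitivity tracks the phase retardation, which grows toward
#' short wavelengths for a normally dispersive mesogen, so the flag is
#' expected at the blue end of the examined range.
#'
#' @param models List of linear-form `calibration_model`s, one per
#'   wavelength (at least two).
#' @param convention LOD convention passed to [limit_of_detection()].
#' @return Data frame sorted by wavelength with columns `wavelength_nm`,
#'   `slope`, `abs_slope`, `lod_g_per_mL`, `most_sensitive`.
#' @export
wavelength_sensitivity_scan <- function(models,
                                        convention = c("abscissa-domain",
                                                       "signal-domain")) {
  convention <- match.arg(convention)
  stopifnot(is.list(models),
            all(vapply(models, inherits, logical(1), "calibration_model")))
  if (length(models) < 2)
    stop("wavelength_sensitivity_scan: need calibration models at >= 2 wavelengths")
  if (any(vapply(models, function(m) m$form, character(1)) != "linear"))
    stop("wavelength_sensitivity_scan: all models must be linear form")
  out <- data.frame(
    wavelength_nm = vapply(models, function(m) m$wavelength_nm, numeric(1)),
    slope = vapply(models, function(m) m$slope, numeric(1)),
    lod_g_per_mL = vapply(models, function(m)
      limit_of_detection(m, convention)$lod_concentration, numeric(1)))
  out$abs_slope <- abs(out$slope)
  out <- out[order(out$wavelength_nm), c("wavelength_nm", "slope",
                                         "abs_slope", "lod_g_per_mL")]
  out$most_sensitive <- out$abs_slope >= max(out$abs_slope) - 1e-15
  rownames(out) <- NULL
  out
}
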