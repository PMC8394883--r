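#' Two-term Cauchy dispersion model for a uniaxial liquid crystal
#'
#' Holds the wavelength dependence of the two principal refractive indices of
#' the mesogen, each as a two-term Cauchy form \eqn{n(\lambda) = A +
#' B/\lambda^2} with \eqn{\lambda} in nanometres, together with the wavelength
#' interval on which the coefficients are considered valid.
#'
#' @param n_parallel_coeffs Numeric vector `c(A, B)` for the extraordinary
#'   index \eqn{n_\parallel(\lambda)} (field parallel to the director).
#'   `A` is dimensionless, `B` has units of nm^2.
#' @param n_perp_coeffs Numeric vector `c(A, B)` for the ordinary index
#'   \eqn{n_\perp(\lambda)} (field perpendicular to the director).
#' @param valid_range Length-2 numeric, wavelength interval in nm on which
#'   the model may be evaluated.
#'
#' @details The birefringence \eqn{\Delta n(\lambda) = n_{\mathrm{eff}} -
#'   n_\perp} must keep a constant sign over `valid_range`; this is checked at
#'   construction. Disodium cromoglycate (DSCG) in its nematic phase is
#'   optically negative (\eqn{n_\parallel < n_\perp}), so \eqn{\Delta n < 0}
#'   is the expected sign; all transmittances depend on \eqn{\Delta n} only
#'   through \eqn{\sin^2(\delta/2)} and are therefore sign-blind.
#'
#' @return An object of class `dispersion_model`.
#' @seealso [dscg_dispersion()] for the package default, [effective_index()],
#'   [birefringence()].
#' @export
dispersion_model <- function(n_parallel_coeffs, n_perp_coeffs,
                             valid_range = c(400, 800)) {
  stopifnot(length(n_parallel_coeffs) == 2, length(n_perp_coeffs) == 2,
            length(valid_range) == 2, valid_range[1] < valid_range[2],
            all(is.finite(c(n_parallel_coeffs, n_perp_coeffs, valid_range))))
  m <- structure(
    list(n_parallel_coeffs = as.numeric(n_parallel_coeffs),
         n_perp_coeffs = as.numeric(n_perp_coeffs),
         valid_range = as.numeric(valid_range)),
    class = "dispersion_model")
  grid <- seq(valid_range[1], valid_range[2], length.out = 101)
  npar <- cauchy_index(m$n_parallel_coeffs, grid)
  nper <- cauchy_index(m$n_perp_coeffs, grid)
  if (any(!is.finite(npar)) || any(!is.finite(nper)) ||
      any(npar <= 1) || any(nper <= 1))
    stop("dispersion_model: indices must be finite and > 1 over valid_range")
  dn <- npar - nper
  if (any(dn > 0) && any(dn < 0))
    stop("dispersion_model: birefringence changes sign over valid_range")
  m
}

#' Default DSCG-like dispersion
#'
#' Package default Cauchy coefficients for nematic DSCG (14 wt% aqueous).
#' The coefficients are synthetic package constants, not measured values:
#' they are chosen to give a small negative birefringence whose magnitude,
#' about 0.015-0.020, decreases with wavelength across the visible range,
#' the behaviour expected of this optically negative chromonic mesogen.
#'
#' @return A `dispersion_model` valid on 400-800 nm with
#'   \eqn{n_\parallel = 1.517 + 3000/\lambda^2} and
#'   \eqn{n_\perp = 1.530 + 4000/\lambda^2}.
#' @export
dscg_dispersion <- function() {
  dispersion_model(n_parallel_coeffs = c(1.517, 3000),
                   n_perp_coeffs = c(1.530, 4000),
                   valid_range = c(400, 800))
}

cauchy_index <- function(coeffs, wavelength_nm) {
  coeffs[1] + coeffs[2] / wavelength_nm^2
}

check_in_range <- function(dispersion, wavelength_nm) {
  r <- dispersion$valid_range
  bad <- wavelength_nm < r[1] | wavelength_nm > r[2]
  if (any(bad))
    stop(sprintf(
      "wavelength(s) %s nm outside the dispersion model's valid range [%g, %g] nm",
      paste(format(wavelength_nm[bad][seq_len(min(5, sum(bad)))]), collapse = ", "),
      r[1], r[2]))
  invisible(TRUE)
}

#' Principal refractive indices at given wavelengths
#'
#' @param dispersion A [dispersion_model()].
#' @param wavelength_nm Wavelengths in nm, within the model's valid range.
#' @return Numeric vector of indices.
#' @export
index_parallel <- function(dispersion, wavelength_nm) {
  check_in_range(dispersion, wavelength_nm)
  cauchy_index(dispersion$n_parallel_coeffs, wavelength_nm)
}

#' @rdname index_parallel
#' @export
index_perp <- function(dispersion, wavelength_nm) {
  check_in_range(dispersion, wavelength_nm)
  cauchy_index(dispersion$n_perp_coeffs, wavelength_nm)
}

#' Effective refractive index of a tilted uniaxial director
#'
#' For light propagating normal to the cell, a director tilted by the polar
#' pretilt angle \eqn{\theta} out of the substrate plane presents the
#' effective extraordinary index
#' \deqn{n_{\mathrm{eff}} = \frac{n_\perp n_\parallel}
#'   {\sqrt{n_\parallel^2 \sin^2\theta + n_\perp^2 \cos^2\theta}},}
#' which collapses to \eqn{n_\parallel} at \eqn{\theta = 0} (planar
#' alignment, maximal birefringence) and to \eqn{n_\perp} at
#' \eqn{\theta = \pi/2} (vertical alignment, vanished birefringence).
#'
#' @param dispersion A [dispersion_model()].
#' @param theta Pretilt angle in radians, in `[0, pi/2]`.
#' @param wavelength_nm Wavelength(s) in nm within the valid range.
#' @return Effective index (numeric, vectorized over wavelength).
#' @export
effective_index <- function(dispersion, theta, wavelength_nm) {
  stopifnot(is.numeric(theta), length(theta) == 1, theta >= 0, theta <= pi / 2)
  npar <- index_parallel(dispersion, wavelength_nm)
  nper <- index_perp(dispersion, wavelength_nm)
  # exact analytic limits at the endpoints (the general expression agrees
  # only to rounding there)
  if (theta == 0) return(npar)
  if (theta == pi / 2) return(nper)
  nper * npar / sqrt(npar^2 * sin(theta)^2 + nper^2 * cos(theta)^2)
}

#' Birefringence seen by normally incident light
#'
#' \eqn{\Delta n(\lambda, \theta) = n_{\mathrm{eff}}(\lambda, \theta) -
#' n_\perp(\lambda)}. The sign is preserved (negative for an optically
#' negative mesogen such as DSCG).
#'
#' @inheritParams effective_index
#' @param theta Pretilt angle in radians (default 0: planar alignment).
#' @return Signed birefringence, vectorized over wavelength.
#' @export
birefringence <- function(dispersion, wavelength_nm, theta = 0) {
  effective_index(dispersion, theta, wavelength_nm) -
    index_perp(dispersion, wavelength_nm)
}

#' Physical state of the sensing cell
#'
#' Bundles the cell gap, director pretilt, in-plane (azimuthal) director
#' angle and the index dispersion of the mesogen. Angles are given in
#' degrees at this user-facing constructor and stored in radians.
#'
#' @param gap_nm Cell gap \eqn{d} in nm (> 0). The reference cells use
#'   15 um rod spacers, i.e. `gap_nm = 15000`.
#' @param pretilt_deg Polar angle \eqn{\theta} between director and substrate
#'   plane, degrees in `[0, 90]`. 0 = planar, 90 = vertical.
#' @param azimuth_deg In-plane angle \eqn{\phi} between director and the
#'   analyzer transmission axis, degrees in `[0, 90]`. The analyte-free
#'   planar ground state has \eqn{\phi = 0}.
#' @param dispersion A [dispersion_model()]; defaults to [dscg_dispersion()].
#' @return An object of class `cell_optics` with fields `gap_nm`,
#'   `pretilt_theta` and `azimuth_phi` (radians), and `dispersion`.
#' @export
cell_optics <- function(gap_nm = 15000, pretilt_deg = 0, azimuth_deg = 0,
                        dispersion = dscg_dispersion()) {
  stopifnot(is.numeric(gap_nm), length(gap_nm) == 1, gap_nm > 0,
            pretilt_deg >= 0, pretilt_deg <= 90,
            azimuth_deg >= 0, azimuth_deg <= 90,
            inherits(dispersion, "dispersion_model"))
  structure(
    list(gap_nm = gap_nm,
         pretilt_theta = pretilt_deg * pi / 180,
         azimuth_phi = azimuth_deg * pi / 180,
         dispersion = dispersion),
    class = "cell_optics")
}

#' @export
print.cell_optics <- function(x, ...) {
  cat(sprintf("<cell_optics> gap %.0f nm, pretilt %.2f deg, azimuth %.2f deg\n",
              x$gap_nm, x$pretilt_theta * 180 / pi, x$azimuth_phi * 180 / pi))
  invisible(x)
}

#' Phase retardation of the cell
#'
#' \eqn{\delta(\lambda) = 2\pi d \, \Delta n(\lambda, \theta) / \lambda},
#' the optical path difference accumulated between the two eigenpolarizations
#' crossing the cell. The sign of \eqn{\Delta n} is preserved.
#'
#' @param cell A [cell_optics()].
#' @param wavelength_nm Wavelength(s) in nm within the dispersion's valid
#'   range.
#' @return Retardation in radians, vectorized over wavelength.
#' @export
phase_retardation <- function(cell, wavelength_nm) {
  stopifnot(inherits(cell, "cell_optics"))
  dn <- birefringence(cell$dispersion, wavelength_nm, cell$pretilt_theta)
  2 * pi * cell$gap_nm * dn / wavelength_nm
}
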