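#' Transmittance of a uniform birefringent cell between polarizers
#'
#' Single-retarder (uniform-director) transmittance of the liquid-crystal
#' cell placed between two linear polarizers, with the entrance polarizer
#' along the rubbing direction:
#' \deqn{I_\parallel = 1 - \sin^2(2\phi)\,\sin^2(\delta/2)}
#' for parallel polarizers and
#' \deqn{I_\perp = \sin^2(2\phi)\,\sin^2(\delta/2)}
#' for crossed polarizers, where \eqn{\phi} is the azimuthal angle of the
#' director from the analyzer transmission axis and \eqn{\delta} the phase
#' retardation. Both depend on \eqn{\delta} only through
#' \eqn{\sin^2(\delta/2)} and are therefore even in \eqn{\delta} (the sign
#' of the birefringence is irrelevant), and they sum to 1 identically.
#'
#' These are physics-level functions: both angles are in radians.
#'
#' @param phi Azimuthal angle in radians.
#' @param delta Phase retardation in radians.
#' @return Transmittance in `[0, 1]`, vectorized over the longer argument.
#' @export
transmittance_parallel <- function(phi, delta) {
  stopifnot(all(is.finite(phi)), all(is.finite(delta)))
  1 - sin(2 * phi)^2 * sin(delta / 2)^2
}

#' @rdname transmittance_parallel
#' @export
transmittance_crossed <- function(phi, delta) {
  stopifnot(all(is.finite(phi)), all(is.finite(delta)))
  sin(2 * phi)^2 * sin(delta / 2)^2
}

# Jones matrix of a linear retarder with fast axis at angle phi and
# retardation delta: R(phi) diag(e^{-i d/2}, e^{+i d/2}) R(-phi).
retarder_jones <- function(phi, delta) {
  c <- cos(phi); s <- sin(phi)
  e1 <- exp(-1i * delta / 2); e2 <- exp(1i * delta / 2)
  matrix(c(c^2 * e1 + s^2 * e2, c * s * (e1 - e2),
           c * s * (e1 - e2), s^2 * e1 + c^2 * e2),
         nrow = 2, byrow = TRUE)
}

#' Transmittance of a stack of retarder slabs (Jones calculus)
#'
#' Composite transmittance of several birefringent slabs with individual
#' azimuths and retardations, between the same polarizer geometries as
#' [transmittance_parallel()]. Computed by multiplying 2x2 complex Jones
#' matrices. A stack with a uniform azimuth collapses exactly to the
#' single-retarder formulas with the summed retardation; with a varying
#' azimuth it models the twisted region that forms above immobilized
#' biomolecules while the far substrate keeps planar anchoring.
#'
#' @param slab_phis Azimuth of each slab, radians (in beam order).
#' @param slab_deltas Retardation of each slab, radians; same length.
#' @param scheme `"parallel"` or `"crossed"`.
#' @return Scalar transmittance in `[0, 1]`.
#' @export
jones_stack_transmittance <- function(slab_phis, slab_deltas,
                                      scheme = c("parallel", "crossed")) {
  scheme <- match.arg(scheme)
  n <- length(slab_phis)
  if (n == 0 || length(slab_deltas) != n)
    stop("jones_stack_transmittance: slab_phis and slab_deltas must have equal nonzero length")
  m <- diag(2)
  for (k in seq_len(n))   # light traverses slab 1 first
    m <- retarder_jones(slab_phis[k], slab_deltas[k]) %*% m
  e_out <- m %*% c(1, 0)  # entrance polarizer along x
  if (scheme == "parallel") Mod(e_out[1])^2 else Mod(e_out[2])^2
}

#' Estimate the azimuthal angle from a parallel/crossed spectrum pair
#'
#' Inverts the single-retarder model: at every wavelength
#' \eqn{I_\perp = \sin^2(2\phi)\,\sin^2(\delta/2)} and
#' \eqn{1 - I_\parallel} equals the same quantity, so with \eqn{\delta(\lambda)}
#' known from the cell parameters, \eqn{a = \sin^2(2\phi)} is obtained by
#' least squares over all admissible wavelengths (both channels pooled),
#' then \eqn{\phi = \tfrac12 \arcsin\sqrt{a}}.
#'
#' Wavelengths where \eqn{\sin^2(\delta/2)} falls below `floor` are excluded:
#' near half-wave nulls the azimuth is unidentifiable. The estimate is
#' reported on the principal branch `[0, 45]` degrees; \eqn{\sin^2(2\phi)} is
#' symmetric about 45 degrees, so an azimuth of e.g. 70 degrees aliases to
#' 20 degrees and the alias is not resolved.
#'
#' @param s_par,s_cross Parallel and crossed `lclc_spectrum` on one grid.
#' @param cell A [cell_optics()] supplying gap, pretilt and dispersion (its
#'   azimuth field is ignored -- that is the unknown).
#' @param floor Minimum admissible \eqn{\sin^2(\delta/2)} (default `1e-3`).
#' @return List with `phi_rad`, `phi_deg`, `residual` (root-mean-square
#'   misfit over the pooled channels) and `n_used` wavelengths.
#' @export
estimate_phi <- function(s_par, s_cross, cell, floor = 1e-3) {
  stopifnot(inherits(s_par, "lclc_spectrum"), inherits(s_cross, "lclc_spectrum"))
  if (!isTRUE(all.equal(s_par$wavelength_nm, s_cross$wavelength_nm)))
    stop("estimate_phi: the two spectra must share one wavelength grid")
  w <- sin(phase_retardation(cell, s_par$wavelength_nm) / 2)^2
  keep <- w >= floor
  if (!any(keep))
    stop("estimate_phi: all wavelengths below the sin^2(delta/2) floor; azimuth unidentifiable")
  w <- w[keep]
  y <- c(s_cross$transmittance[keep], 1 - s_par$transmittance[keep])
  ww <- c(w, w)
  a <- sum(ww * y) / sum(ww^2)      # LS slope through origin: y = a * w
  a <- min(max(a, 0), 1)            # physical range of sin^2(2 phi)
  phi <- 0.5 * asin(sqrt(a))
  list(phi_rad = phi, phi_deg = phi * 180 / pi,
       residual = sqrt(mean((y - a * ww)^2)), n_used = sum(keep))
}
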