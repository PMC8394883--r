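#' Detect interference fringes in an empty-cell spectrum
#'
#' Finds local transmittance maxima whose topographic prominence (height
#' above the higher of the two saddles separating the peak from taller
#' peaks) exceeds `prominence`. Prominence-based detection makes the fringe
#' set invariant to multiplication of the spectrum by a smooth positive
#' envelope, which matters because real lamp/detector envelopes are far
#' from flat.
#'
#' Peak positions are refined to sub-grid accuracy by fitting a parabola
#' through each maximum and its two neighbours.
#'
#' @param spec An `lclc_spectrum`, approximately periodic in
#'   \eqn{1/\lambda} (at least 16 samples).
#' @param prominence Minimum prominence, in transmittance units
#'   (default 0.1).
#' @return An object of class `fringe_set`: `extrema_wavelengths`
#'   (increasing, nm), `kind = "maxima"`, `source_grid` (analyzed interval),
#'   `grid_step` (median sample spacing, nm).
#' @export
detect_fringes <- function(spec, prominence = 0.1) {
  stopifnot(inherits(spec, "lclc_spectrum"))
  w <- spec$wavelength_nm
  v <- spec$transmittance
  n <- length(v)
  if (n < 16) stop("detect_fringes: need at least 16 samples")
  is_max <- which(diff(sign(diff(v))) < 0) + 1L
  if (length(is_max) > 0) {
    prom <- vapply(is_max, function(i) {
      peak <- v[i]
      left <- v[seq_len(i - 1)]
      right <- v[seq(i + 1, n)]
      higher_l <- which(left >= peak)
      higher_r <- which(right >= peak)
      saddle_l <- if (length(higher_l)) min(left[seq(max(higher_l), i - 1)]) else min(left)
      saddle_r <- if (length(higher_r)) min(right[seq_len(min(higher_r))]) else min(right)
      peak - min(max(saddle_l, saddle_r), peak)
    }, numeric(1))
    is_max <- is_max[prom >= prominence]
  }
  if (length(is_max) < 2)
    stop("detect_fringes: fewer than 2 fringe maxima found; spectrum carries insufficient fringes")
  # parabolic sub-grid refinement of each peak position
  refined <- vapply(is_max, function(i) {
    if (i == 1L || i == n) return(w[i])
    y1 <- v[i - 1]; y2 <- v[i]; y3 <- v[i + 1]
    denom <- y1 - 2 * y2 + y3
    if (denom == 0) return(w[i])
    off <- 0.5 * (y1 - y3) / denom
    off <- max(min(off, 0.5), -0.5)
    w[i] + off * (w[min(i + 1, n)] - w[max(i - 1, 1)]) / 2
  }, numeric(1))
  structure(
    list(extrema_wavelengths = sort(refined), kind = "maxima",
         source_grid = range(w), grid_step = stats::median(diff(w))),
    class = "fringe_set")
}

#' Estimate the cell gap from interference fringes
#'
#' Two-beam interference in a thin cavity of gap \eqn{d} and medium index
#' \eqn{n} puts transmittance maxima at \eqn{\lambda = 2 n d / m} for
#' integer fringe order \eqn{m}. Counting the \eqn{N} fringe intervals
#' between the first (\eqn{\lambda_1}) and last (\eqn{\lambda_N}) detected
#' maxima gives the standard fringe-counting estimate
#' \deqn{d = \frac{N \, \lambda_1 \lambda_N}{2 n (\lambda_N - \lambda_1)}.}
#' Only interval counts are used; no absolute fringe order is assigned, so
#' the estimate is robust to the spectral envelope. The uncertainty is
#' propagated from the per-peak wavelength resolution.
#'
#' @param fringes A [detect_fringes()] result with at least 2 maxima.
#' @param medium_index Refractive index of the cavity medium (default 1,
#'   the empty air-filled cell measured before filling).
#' @param wavelength_resolution Per-peak 1-sigma wavelength uncertainty in
#'   nm; defaults to half the source grid step.
#' @return List with `gap_nm`, `sd_nm`, `n_intervals`, `lambda_first`,
#'   `lambda_last`.
#' @export
estimate_gap <- function(fringes, medium_index = 1,
                         wavelength_resolution = NULL) {
  stopifnot(inherits(fringes, "fringe_set"), medium_index >= 1)
  wl <- fringes$extrema_wavelengths
  if (length(wl) < 2) stop("estimate_gap: need at least 2 fringe maxima")
  l1 <- wl[1]; ln <- wl[length(wl)]
  if (ln == l1) stop("estimate_gap: degenerate fringe set (identical wavelengths)")
  n_int <- length(wl) - 1
  d <- n_int * l1 * ln / (2 * medium_index * (ln - l1))
  if (is.null(wavelength_resolution))
    wavelength_resolution <- fringes$grid_step / 2
  # d depends on lambda_1 and lambda_N only; first-order propagation
  dd_dl1 <- d * (1 / l1 + 1 / (ln - l1))
  dd_dln <- d * (1 / ln - 1 / (ln - l1))
  sd_d <- sqrt(dd_dl1^2 + dd_dln^2) * wavelength_resolution
  list(gap_nm = d, sd_nm = sd_d, n_intervals = n_int,
       lambda_first = l1, lambda_last = ln)
}
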