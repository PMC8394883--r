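#' Polarized transmission spectrum
#'
#' A transmittance-vs-wavelength record tagged with its acquisition
#' geometry. Transmittance is dimensionless (instrument-normalized); values
#' slightly above 1 can occur under noise and are not clipped.
#'
#' @param wavelength_nm Strictly increasing wavelength grid, nm.
#' @param transmittance Transmittance values, one per wavelength, finite.
#' @param scheme `"parallel"` or `"crossed"` polarizer geometry.
#' @param condition `"with-analyte"` or `"analyte-free"`.
#' @param replicate_id Integer replicate identifier.
#' @return An object of class `lclc_spectrum`.
#' @export
spectrum <- function(wavelength_nm, transmittance,
                     scheme = c("parallel", "crossed"),
                     condition = c("analyte-free", "with-analyte"),
                     replicate_id = 1L) {
  scheme <- match.arg(scheme)
  condition <- match.arg(condition)
  wavelength_nm <- as.numeric(wavelength_nm)
  transmittance <- as.numeric(transmittance)
  if (length(wavelength_nm) == 0)
    stop("spectrum: empty wavelength grid")
  if (length(wavelength_nm) != length(transmittance))
    stop("spectrum: wavelength and transmittance lengths differ")
  if (any(diff(wavelength_nm) <= 0))
    stop("spectrum: wavelengths must be strictly increasing")
  if (any(!is.finite(transmittance)))
    stop("spectrum: transmittance values must be finite")
  structure(
    list(wavelength_nm = wavelength_nm, transmittance = transmittance,
         scheme = scheme, condition = condition,
         replicate_id = as.integer(replicate_id)),
    class = "lclc_spectrum")
}

#' @export
print.lclc_spectrum <- function(x, ...) {
  cat(sprintf(
    "<lclc_spectrum> %s polarizers, %s, replicate %d: %d points, %g-%g nm\n",
    x$scheme, x$condition, x$replicate_id, length(x$wavelength_nm),
    min(x$wavelength_nm), max(x$wavelength_nm)))
  invisible(x)
}

#' Simulate a transmission spectrum of the uniform-director cell
#'
#' Vectorizes the single-retarder transmittance formulas over a wavelength
#' grid: at each wavelength the retardation is computed from the cell's gap,
#' pretilt and dispersion, and the parallel- or crossed-polarizer
#' transmittance is evaluated at the cell's azimuthal angle.
#'
#' @param cell A [cell_optics()].
#' @param grid Wavelength grid in nm (strictly increasing, within the
#'   dispersion's valid range).
#' @param scheme `"parallel"` or `"crossed"`.
#' @param condition,replicate_id Metadata passed to [spectrum()].
#' @return An `lclc_spectrum`.
#' @export
simulate_spectrum <- function(cell, grid, scheme = c("parallel", "crossed"),
                              condition = "analyte-free", replicate_id = 1L) {
  scheme <- match.arg(scheme)
  if (length(grid) == 0) stop("simulate_spectrum: empty wavelength grid")
  delta <- phase_retardation(cell, grid)
  values <- if (scheme == "parallel")
    transmittance_parallel(cell$azimuth_phi, delta)
  else
    transmittance_crossed(cell$azimuth_phi, delta)
  spectrum(grid, values, scheme = scheme, condition = condition,
           replicate_id = replicate_id)
}

#' Write / read the plain-text spectrum format
#'
#' Two tab-separated columns (`wavelength_nm`, `transmittance`) preceded by
#' `#`-prefixed header lines carrying the scheme, condition and replicate
#' metadata, so a file round-trips to an identical object.
#'
#' @param x An `lclc_spectrum`.
#' @param path File path.
#' @return `write_spectrum` returns `path` invisibly; `read_spectrum`
#'   returns an `lclc_spectrum`.
#' @export
write_spectrum <- function(x, path) {
  stopifnot(inherits(x, "lclc_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# scheme: %s", x$scheme),
               sprintf("# condition: %s", x$condition),
               sprintf("# replicate_id: %d", x$replicate_id),
               "wavelength_nm\ttransmittance"), con)
  utils::write.table(
    data.frame(w = sprintf("%.10g", x$wavelength_nm),
               t = sprintf("%.10g", x$transmittance)),
    con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  get_meta <- function(key, default) {
    m <- grep(sprintf("^# %s:", key), hdr, value = TRUE)
    if (length(m) == 0) return(default)
    trimws(sub(sprintf("^# %s:", key), "", m[1]))
  }
  tab <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                           sep = "\t")
  spectrum(tab$wavelength_nm, tab$transmittance,
           scheme = get_meta("scheme", "parallel"),
           condition = get_meta("condition", "analyte-free"),
           replicate_id = as.integer(get_meta("replicate_id", "1")))
}

#' Resample a spectrum onto a new wavelength grid
#'
#' Linear interpolation onto `grid`. Provided as an explicit utility:
#' [reduce_transmittance()] requires exactly matching grids and never
#' resamples silently, so instrument drift between acquisitions stays
#' visible.
#'
#' @param x An `lclc_spectrum`.
#' @param grid Target grid in nm; must lie within the source grid's span
#'   (no extrapolation).
#' @return An `lclc_spectrum` on `grid`.
#' @export
resample_spectrum <- function(x, grid) {
  stopifnot(inherits(x, "lclc_spectrum"))
  if (min(grid) < min(x$wavelength_nm) || max(grid) > max(x$wavelength_nm))
    stop("resample_spectrum: target grid extends beyond the source grid")
  v <- stats::approx(x$wavelength_nm, x$transmittance, xout = grid)$y
  spectrum(grid, v, scheme = x$scheme, condition = x$condition,
           replicate_id = x$replicate_id)
}
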