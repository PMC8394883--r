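#' Reduced transmittance of an analyte-bearing cell
#'
#' Normalizes the raw with-analyte spectra against the analyte-free
#' references acquired on the same optics, mapping the blank to
#' \eqn{(T_\parallel, T_\perp) = (1, 0)}:
#' \deqn{T_\parallel(\lambda) = \frac{S_\parallel - T_\perp^{w/o}}
#'   {T_\parallel^{w/o} - T_\perp^{w/o}}, \qquad
#'   T_\perp(\lambda) = \frac{S_\perp - T_\perp^{w/o}}
#'   {T_\parallel^{w/o} - T_\perp^{w/o}},}
#' where \eqn{S} are the with-analyte and \eqn{T^{w/o}} the analyte-free
#' transmittances in the respective polarizer schemes. The ratio
#' \eqn{T_\parallel / T_\perp} is also computed where it is defined.
#'
#' All four spectra must share exactly one wavelength grid; use
#' [resample_spectrum()] explicitly if they do not. Values are never
#' clipped: under noise they may fall slightly outside `[0, 1]`, which is
#' legitimate. The ratio is set to `NA` (not infinity) wherever
#' \eqn{|T_\perp|} falls below `ratio_floor` -- at blank-like conditions
#' \eqn{T_\perp \to 0} and the ratio diverges, which is why ratio
#' calibrations use only analyte-bearing concentrations.
#'
#' @param s_par,s_cross With-analyte spectra, parallel and crossed schemes.
#' @param ref_par,ref_cross Analyte-free reference spectra.
#' @param concentration Analyte mass concentration in g/mL (0 for blanks).
#' @param analyte_label Free-text analyte name.
#' @param ref_floor Minimum allowed \eqn{|T_\parallel^{w/o} - T_\perp^{w/o}|}
#'   per wavelength (default `1e-6`); a reference pair closer than this is
#'   degenerate and rejected.
#' @param ratio_floor \eqn{|T_\perp|} below which the ratio is `NA`
#'   (default `1e-9`).
#' @return An object of class `reduced_transmittance`: a data frame with
#'   columns `wavelength_nm`, `T_parallel`, `T_crossed`, `ratio`, and
#'   attributes `concentration` and `analyte_label`.
#' @export
reduce_transmittance <- function(s_par, s_cross, ref_par, ref_cross,
                                 concentration = NA_real_,
                                 analyte_label = "",
                                 ref_floor = 1e-6, ratio_floor = 1e-9) {
  specs <- list(s_par, s_cross, ref_par, ref_cross)
  stopifnot(all(vapply(specs, inherits, logical(1), "lclc_spectrum")))
  grid <- s_par$wavelength_nm
  for (s in specs[-1]) {
    if (length(s$wavelength_nm) != length(grid) ||
        any(s$wavelength_nm != grid)) {
      off <- if (length(s$wavelength_nm) == length(grid))
        grid[s$wavelength_nm != grid] else numeric(0)
      stop(sprintf(
        "reduce_transmittance: wavelength grids differ%s; resample explicitly with resample_spectrum()",
        if (length(off)) sprintf(" (first offending wavelengths: %s nm)",
                                 paste(utils::head(off, 5), collapse = ", "))
        else ""))
    }
  }
  denom <- ref_par$transmittance - ref_cross$transmittance
  bad <- abs(denom) < ref_floor
  if (any(bad))
    stop(sprintf(
      "reduce_transmittance: degenerate reference (|ref_par - ref_cross| < %g) at %d wavelength(s), e.g. %s nm",
      ref_floor, sum(bad), paste(utils::head(grid[bad], 5), collapse = ", ")))
  t_par <- (s_par$transmittance - ref_cross$transmittance) / denom
  t_cross <- (s_cross$transmittance - ref_cross$transmittance) / denom
  ratio <- ifelse(abs(t_cross) < ratio_floor, NA_real_, t_par / t_cross)
  out <- data.frame(wavelength_nm = grid, T_parallel = t_par,
                    T_crossed = t_cross, ratio = ratio)
  attr(out, "concentration") <- concentration
  attr(out, "analyte_label") <- analyte_label
  class(out) <- c("reduced_transmittance", "data.frame")
  out
}

#' Average reduced-transmittance replicates at one concentration
#'
#' Per-wavelength sample mean and sample standard deviation (n - 1
#' denominator) of `T_parallel`, `T_crossed` and `ratio` across replicate
#' records of the same concentration.
#'
#' @param records List of `reduced_transmittance` objects with identical
#'   wavelength grids and concentrations.
#' @return Data frame with per-wavelength `*_mean` and `*_sd` columns and
#'   attributes `n`, `concentration`, `analyte_label` and
#'   `single_replicate` (`TRUE`, with a warning, when n = 1; sd is then 0
#'   by convention).
#' @export
aggregate_replicates <- function(records) {
  stopifnot(is.list(records), length(records) >= 1,
            all(vapply(records, inherits, logical(1), "reduced_transmittance")))
  grid <- records[[1]]$wavelength_nm
  conc <- attr(records[[1]], "concentration")
  for (r in records[-1]) {
    if (length(r$wavelength_nm) != length(grid) || any(r$wavelength_nm != grid))
      stop("aggregate_replicates: records have differing wavelength grids")
    if (!isTRUE(all.equal(attr(r, "concentration"), conc)))
      stop("aggregate_replicates: records mix different concentrations")
  }
  n <- length(records)
  single <- n == 1
  if (single)
    warning("aggregate_replicates: single replicate; sd reported as 0 by convention")
  col_stats <- function(col) {
    m <- vapply(records, function(r) r[[col]], numeric(length(grid)))
    m <- matrix(m, nrow = length(grid))
    list(mean = rowMeans(m),
         sd = if (single) rep(0, length(grid)) else apply(m, 1, stats::sd))
  }
  tp <- col_stats("T_parallel"); tc <- col_stats("T_crossed")
  rt <- col_stats("ratio")
  out <- data.frame(wavelength_nm = grid,
                    T_parallel_mean = tp$mean, T_parallel_sd = tp$sd,
                    T_crossed_mean = tc$mean, T_crossed_sd = tc$sd,
                    ratio_mean = rt$mean, ratio_sd = rt$sd)
  attr(out, "n") <- n
  attr(out, "concentration") <- conc
  attr(out, "analyte_label") <- attr(records[[1]], "analyte_label")
  attr(out, "single_replicate") <- single
  out
}

#' Write a reduced-transmittance record as delimited text
#'
#' Columns `wavelength_nm`, `T_parallel`, `T_crossed`, `ratio`, preceded by
#' `#`-prefixed metadata lines (concentration, analyte).
#'
#' @param x A `reduced_transmittance`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_reduced <- function(x, path) {
  stopifnot(inherits(x, "reduced_transmittance"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# concentration_g_per_mL: %.10g", attr(x, "concentration")),
               sprintf("# analyte: %s", attr(x, "analyte_label"))), con)
  utils::write.table(as.data.frame(x), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
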