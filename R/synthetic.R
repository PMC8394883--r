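#' Dose-response link between analyte concentration and director azimuth
#'
#' The generator needs a monotone map from analyte mass concentration to
#' the azimuthal disturbance \eqn{\phi} of the planar director. No
#' measured functional form exists for this map (only transmittances are
#' observed in practice), so the package uses a synthetic logistic in
#' log10 concentration,
#' \deqn{\phi(c) = \frac{\phi_{max}}{1 + 10^{-h (\log_{10} c - \log_{10} c_{50})}},
#'   \qquad \phi(0) = 0,}
#' chosen because it reproduces the qualitative behaviour a dilution
#' series shows: a blank-like plateau at trace concentrations and
#' saturation at high load, i.e. the S-shape that makes cubic calibration
#' curves appropriate over a wide concentration range.
#'
#' \eqn{\phi_{max}} is capped at 45 degrees so generated data stay on the
#' identifiable branch of the transmittance formulas.
#'
#' @param phi_max_deg Saturating azimuth, degrees (0-45]. Default 40.
#' @param c50 Midpoint concentration in g/mL. Default `10^-8.5`.
#' @param hill Logistic steepness per decade. Default 0.25, a gentle
#'   sigmoid spanning the 8-decade series.
#' @return An object of class `dose_response_link` (phi_max stored in
#'   radians).
#' @export
dose_response_link <- function(phi_max_deg = 40, c50 = 10^-8.5, hill = 0.25) {
  stopifnot(phi_max_deg > 0, phi_max_deg <= 45, c50 > 0, hill > 0)
  structure(list(phi_max = phi_max_deg * pi / 180, c50 = c50, hill = hill,
                 form = "logistic-in-log10c"),
            class = "dose_response_link")
}

#' Azimuthal angle produced by a given analyte concentration
#'
#' Evaluates the logistic link; \eqn{\phi(0) = 0} by continuity (the blank
#' leaves the planar alignment untouched).
#'
#' @param link A [dose_response_link()].
#' @param concentration Concentration(s) in g/mL, >= 0.
#' @return Azimuth in radians, vectorized.
#' @export
phi_of_concentration <- function(link, concentration) {
  stopifnot(inherits(link, "dose_response_link"), all(concentration >= 0))
  out <- numeric(length(concentration))
  pos <- concentration > 0
  out[pos] <- link$phi_max /
    (1 + 10^(-link$hill * (log10(concentration[pos]) - log10(link$c50))))
  out
}

#' Instrument noise model for synthetic spectra
#'
#' Each transmittance value t is perturbed to
#' `t * (1 + e_mult) + e_add` with independent Gaussian draws per
#' wavelength. The defaults give a response standard deviation of about
#' 0.02 on near-unity transmittances, matching the replicate scatter a
#' fiber-optic spectrometer shows on these cells.
#'
#' @param multiplicative_sd Relative sd of the multiplicative term
#'   (default 0.02).
#' @param additive_sd Absolute sd of the additive term, transmittance
#'   units (default 0.002).
#' @param seed Integer seed for the single RNG stream.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(multiplicative_sd = 0.02, additive_sd = 0.002,
                        seed = 1L) {
  stopifnot(multiplicative_sd >= 0, additive_sd >= 0)
  structure(list(multiplicative_sd = multiplicative_sd,
                 additive_sd = additive_sd, seed = as.integer(seed)),
            class = "noise_model")
}

apply_noise <- function(values, noise) {
  n <- length(values)
  e_mult <- stats::rnorm(n, 0, noise$multiplicative_sd)
  e_add <- stats::rnorm(n, 0, noise$additive_sd)
  values * (1 + e_mult) + e_add
}

#' Configuration of a synthetic dilution-series experiment
#'
#' Describes a complete in-silico experiment: a dilution series (default
#' eight decades, 1e-12 to 1e-5 g/mL, mirroring the reference assay
#' design), replicate count, wavelength grid, cell optics, dose-response
#' link and noise model.
#'
#' @param concentrations Strictly increasing positive concentrations,
#'   g/mL.
#' @param replicates Replicates per concentration (>= 3 by convention; the
#'   constructor accepts fewer but the defaults follow the n >= 3 error-bar
#'   convention).
#' @param grid Wavelength grid, nm.
#' @param cell A [cell_optics()] for the analyte-free planar state.
#' @param link A [dose_response_link()].
#' @param noise A [noise_model()].
#' @param analyte_label Analyte name used in file names and metadata.
#' @return An object of class `synthetic_experiment`.
#' @export
synthetic_experiment <- function(concentrations = 10^seq(-12, -5),
                                 replicates = 3L,
                                 grid = seq(400, 800, by = 1),
                                 cell = cell_optics(),
                                 link = dose_response_link(),
                                 noise = noise_model(),
                                 analyte_label = "BSA") {
  stopifnot(all(concentrations > 0), all(diff(concentrations) > 0),
            replicates >= 1, length(grid) >= 2, all(diff(grid) > 0),
            inherits(cell, "cell_optics"),
            inherits(link, "dose_response_link"),
            inherits(noise, "noise_model"))
  structure(list(concentrations = concentrations,
                 replicates = as.integer(replicates), grid = grid,
                 cell = cell, link = link, noise = noise,
                 analyte_label = analyte_label),
            class = "synthetic_experiment")
}

cell_at_phi <- function(cell, phi_rad) {
  out <- cell
  out$azimuth_phi <- phi_rad
  out
}

#' Simulate a synthetic experiment in memory
#'
#' Draws the full experiment with one seeded RNG stream in a documented
#' order: first the analyte-free reference pairs (one parallel + one
#' crossed pair per replicate, at azimuth 0), then, for each concentration
#' in ascending order and each replicate, the with-analyte parallel and
#' crossed spectra at \eqn{\phi(c)}. Within each spectrum the
#' multiplicative noise vector is drawn before the additive one. A fixed
#' seed therefore fully determines every value.
#'
#' @param config A [synthetic_experiment()].
#' @return List with `references` (list of `list(parallel, crossed)` per
#'   replicate), `series` (per concentration: `concentration`, `phi_rad`,
#'   and per replicate `list(parallel, crossed)`), and the `config`.
#' @export
simulate_experiment <- function(config) {
  stopifnot(inherits(config, "synthetic_experiment"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$noise$seed)
  noisy_pair <- function(phi_rad, condition, rep_id) {
    cc <- cell_at_phi(config$cell, phi_rad)
    out <- list()
    for (sch in c("parallel", "crossed")) {
      s <- simulate_spectrum(cc, config$grid, scheme = sch,
                             condition = condition, replicate_id = rep_id)
      s$transmittance <- apply_noise(s$transmittance, config$noise)
      out[[sch]] <- s
    }
    out
  }
  references <- lapply(seq_len(config$replicates), function(r)
    noisy_pair(0, "analyte-free", r))
  series <- lapply(seq_along(config$concentrations), function(i) {
    conc <- config$concentrations[i]
    phi <- phi_of_concentration(config$link, conc)
    list(concentration = conc, phi_rad = phi,
         replicates = lapply(seq_len(config$replicates), function(r)
           noisy_pair(phi, "with-analyte", r)))
  })
  list(references = references, series = series, config = config)
}

#' Generate a synthetic experiment as a file tree
#'
#' Materializes [simulate_experiment()] as the standard plain-text
#' spectrum files plus a tab-separated `manifest.tsv` listing every file
#' with its generating parameters (condition, concentration, azimuth,
#' replicate, scheme, seed). Byte-identical across runs with the same
#' configuration and seed.
#'
#' @param config A [synthetic_experiment()].
#' @param dir Output directory (created if needed).
#' @return The manifest data frame, invisibly.
#' @export
generate_experiment <- function(config, dir) {
  sim <- simulate_experiment(config)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  emit <- function(spec, fname, conc, phi_rad) {
    write_spectrum(spec, file.path(dir, fname))
    rows[[length(rows) + 1]] <<- data.frame(
      file = fname, condition = spec$condition, scheme = spec$scheme,
      replicate_id = spec$replicate_id,
      concentration_g_per_mL = conc, azimuth_deg = phi_rad * 180 / pi,
      seed = config$noise$seed)
  }
  for (r in seq_along(sim$references))
    for (sch in c("parallel", "crossed"))
      emit(sim$references[[r]][[sch]],
           sprintf("ref_%s_rep%d.tsv", sch, r), 0, 0)
  for (s in sim$series)
    for (r in seq_along(s$replicates))
      for (sch in c("parallel", "crossed"))
        emit(s$replicates[[r]][[sch]],
             sprintf("%s_c%0.3e_%s_rep%d.tsv",
                     gsub("[^A-Za-z0-9]", "", config$analyte_label),
                     s$concentration, sch, r),
             s$concentration, s$phi_rad)
  manifest <- do.call(rbind, rows)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(manifest)
}

#' Synthetic empty-cell interference spectrum
#'
#' Two-beam interference transmittance of an empty (air) cavity of the
#' given gap: \eqn{T(\lambda) = \tfrac12 (1 + \cos(4\pi d/\lambda))},
#' which has maxima exactly at \eqn{\lambda = 2d/m}, plus optional
#' instrument noise. A zero-noise, zero-gap input degenerates to a flat
#' spectrum.
#'
#' @param gap_nm Cavity gap in nm, > 0 (0 allowed, giving a flat
#'   spectrum).
#' @param grid Wavelength grid, nm.
#' @param noise A [noise_model()] or `NULL` for noiseless output.
#' @return An `lclc_spectrum`.
#' @export
generate_empty_cell_spectrum <- function(gap_nm, grid, noise = NULL) {
  stopifnot(gap_nm >= 0, length(grid) >= 2)
  v <- 0.5 * (1 + cos(4 * pi * gap_nm / grid))
  if (!is.null(noise)) {
    stopifnot(inherits(noise, "noise_model"))
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(noise$seed)
    v <- apply_noise(v, noise)
  }
  spectrum(grid, v, scheme = "parallel", condition = "analyte-free")
}

#' Refit the logistic dose-response link to azimuth estimates
#'
#' Nonlinear least squares of the logistic-in-log10c link to per-
#' concentration azimuth estimates, used for end-to-end parameter-recovery
#' checks of the whole pipeline (generate, reduce, estimate azimuth,
#' refit).
#'
#' @param concentration Concentrations in g/mL (> 0).
#' @param phi_rad Estimated azimuths in radians.
#' @return A `dose_response_link` with the recovered parameters.
#' @export
fit_dose_response <- function(concentration, phi_rad) {
  stopifnot(length(concentration) == length(phi_rad),
            all(concentration > 0))
  x <- log10(concentration)
  df <- data.frame(x = x, phi = phi_rad)
  start <- list(phi_max = max(phi_rad) * 1.05,
                logc50 = stats::median(x), hill = 0.5)
  fit <- minpack.lm::nlsLM(
    phi ~ phi_max / (1 + 10^(-hill * (x - logc50))),
    data = df, start = start,
    lower = c(phi_max = 1e-6, logc50 = min(x) - 6, hill = 0.01),
    upper = c(phi_max = pi / 4, logc50 = max(x) + 6, hill = 10),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  p <- stats::coef(fit)
  dose_response_link(phi_max_deg = unname(p["phi_max"]) * 180 / pi,
                     c50 = 10^unname(p["logc50"]),
                     hill = unname(p["hill"]))
}
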