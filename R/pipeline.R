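#' Read a run configuration from structured text
#'
#' YAML configuration with the fields accepted by [run_quantitation()]:
#' either a `synthetic:` block (keys `seed`, `replicates`,
#' `log10_conc_min`, `log10_conc_max`, `gap_nm`, `phi_max_deg`, `c50`,
#' `hill`, `multiplicative_sd`, `additive_sd`, `analyte_label`) or an
#' `input_dir:` pointing at a spectrum tree with a `manifest.tsv`; plus
#' `wavelengths`, `lod_convention`, `linear_range_n`, `output_dir`.
#'
#' @param path Path to a YAML file.
#' @return A named list usable as `config` in [run_quantitation()].
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

synthetic_from_block <- function(block) {
  block <- as.list(block)
  g <- function(key, default) if (!is.null(block[[key]])) block[[key]] else default
  synthetic_experiment(
    concentrations = 10^seq(g("log10_conc_min", -12), g("log10_conc_max", -5)),
    replicates = g("replicates", 3L),
    grid = seq(g("grid_min", 400), g("grid_max", 800), by = g("grid_step", 1)),
    cell = cell_optics(gap_nm = g("gap_nm", 15000)),
    link = dose_response_link(phi_max_deg = g("phi_max_deg", 40),
                              c50 = g("c50", 10^-8.5),
                              hill = g("hill", 0.25)),
    noise = noise_model(multiplicative_sd = g("multiplicative_sd", 0.02),
                        additive_sd = g("additive_sd", 0.002),
                        seed = g("seed", 1L)),
    analyte_label = g("analyte_label", "BSA"))
}

read_experiment_dir <- function(dir) {
  mf_path <- file.path(dir, "manifest.tsv")
  if (!file.exists(mf_path))
    stop(sprintf("input directory %s has no manifest.tsv", dir))
  mf <- utils::read.table(mf_path, header = TRUE, sep = "\t")
  load_pair <- function(rows) {
    list(parallel = read_spectrum(file.path(dir, rows$file[rows$scheme == "parallel"])),
         crossed = read_spectrum(file.path(dir, rows$file[rows$scheme == "crossed"])))
  }
  refs <- mf[mf$condition == "analyte-free", ]
  references <- lapply(sort(unique(refs$replicate_id)), function(r)
    load_pair(refs[refs$replicate_id == r, ]))
  ana <- mf[mf$condition == "with-analyte", ]
  concs <- sort(unique(ana$concentration_g_per_mL))
  series <- lapply(concs, function(conc) {
    sub <- ana[ana$concentration_g_per_mL == conc, ]
    list(concentration = conc, phi_rad = NA_real_,
         replicates = lapply(sort(unique(sub$replicate_id)), function(r)
           load_pair(sub[sub$replicate_id == r, ])))
  })
  list(references = references, series = series, config = NULL)
}

reduce_experiment <- function(sim) {
  n_ref <- length(sim$references)
  lapply(sim$series, function(s) {
    recs <- lapply(seq_along(s$replicates), function(r) {
      ref <- sim$references[[((r - 1) %% n_ref) + 1]]
      reduce_transmittance(s$replicates[[r]]$parallel,
                           s$replicates[[r]]$crossed,
                           ref$parallel, ref$crossed,
                           concentration = s$concentration)
    })
    aggregate_replicates(recs)
  })
}

nearest_index <- function(grid, wl) which.min(abs(grid - wl))

#' Run the full quantitation workflow
#'
#' Chains the pipeline end to end: obtain (or generate) the four-way
#' spectra, reduce them against the analyte-free references, aggregate
#' replicates, fit per-wavelength calibration curves for the three
#' response channels, compute limits of detection, scan sensitivity
#' across wavelengths and (optionally) predict unknown-sample
#' concentrations.
#'
#' Per wavelength of interest the report holds: a cubic calibration of
#' `T_parallel` and of `T_crossed` over the full dilution series, a
#' linear calibration of each over the low-concentration linear range
#' (the `linear_range_n` lowest concentrations, default 3) feeding the
#' 3s/m LOD, and a linear calibration of the `ratio` over the full range
#' with its own LOD.
#'
#' @param config A named list (or path handled by [read_run_config()])
#'   with either `synthetic` (block or a `synthetic_experiment`) or
#'   `input_dir`; optional `wavelengths` (default 450-800 nm by 50),
#'   `lod_convention` (default `"abscissa-domain"`), `linear_range_n`
#'   (default 3), `output_dir` (tables and a log are written when given),
#'   `unknowns` (list of `list(parallel=, crossed=)` spectrum pairs).
#' @return An object of class `quantitation_report`: `calibrations`
#'   (data frame), `models` (nested list by wavelength and channel),
#'   `lod_table`, `sensitivity` (per channel), `predictions` (or NULL),
#'   `reduced` records, and `log` (character vector of stage messages).
#' @export
run_quantitation <- function(config) {
  if (is.character(config) && length(config) == 1)
    config <- read_run_config(config)
  g <- function(key, default) if (!is.null(config[[key]])) config[[key]] else default
  wavelengths <- g("wavelengths", seq(450, 800, by = 50))
  convention <- g("lod_convention", "abscissa-domain")
  lin_n <- g("linear_range_n", 3L)
  log_lines <- character(0)
  note <- function(...) log_lines <<- c(log_lines, sprintf(...))

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }

  sim <- stage("input", {
    if (!is.null(config$synthetic)) {
      exp_cfg <- if (inherits(config$synthetic, "synthetic_experiment"))
        config$synthetic else synthetic_from_block(config$synthetic)
      note("input: synthetic experiment, %d concentrations x %d replicates, seed %d",
           length(exp_cfg$concentrations), exp_cfg$replicates,
           exp_cfg$noise$seed)
      simulate_experiment(exp_cfg)
    } else if (!is.null(config$input_dir)) {
      note("input: reading %s", config$input_dir)
      read_experiment_dir(config$input_dir)
    } else stop("config needs either a 'synthetic' block or an 'input_dir'")
  })

  reduced <- stage("reduction", reduce_experiment(sim))
  concs <- vapply(reduced, function(r) attr(r, "concentration"), numeric(1))
  grid <- reduced[[1]]$wavelength_nm
  bad_wl <- wavelengths[wavelengths < min(grid) | wavelengths > max(grid)]
  if (length(bad_wl) > 0)
    stop(sprintf("[config] wavelengths outside the spectral grid: %s nm",
                 paste(bad_wl, collapse = ", ")))

  lin_idx <- order(concs)[seq_len(min(lin_n, length(concs)))]

  models <- list(); cal_rows <- list(); lod_rows <- list()
  stage("calibration", for (wl in wavelengths) {
    i <- nearest_index(grid, wl)
    wl_act <- grid[i]
    pts <- function(col_mean, col_sd) data.frame(
      concentration = concs,
      response = vapply(reduced, function(r) r[[col_mean]][i], numeric(1)),
      response_sd = vapply(reduced, function(r) r[[col_sd]][i], numeric(1)))
    p_par <- pts("T_parallel_mean", "T_parallel_sd")
    p_cro <- pts("T_crossed_mean", "T_crossed_sd")
    p_rat <- pts("ratio_mean", "ratio_sd")
    wl_models <- list(
      T_parallel_cubic = fit_calibration(p_par, "T_parallel", wl_act, "cubic"),
      T_crossed_cubic = fit_calibration(p_cro, "T_crossed", wl_act, "cubic"),
      T_parallel_linear = fit_calibration(p_par[lin_idx, ], "T_parallel",
                                          wl_act, "linear"),
      T_crossed_linear = fit_calibration(p_cro[lin_idx, ], "T_crossed",
                                         wl_act, "linear"),
      ratio_linear = fit_calibration(p_rat, "ratio", wl_act, "linear"))
    models[[as.character(wl)]] <- wl_models
    for (nm in names(wl_models)) {
      m <- wl_models[[nm]]
      cal_rows[[length(cal_rows) + 1]] <- data.frame(
        wavelength_nm = wl_act, channel = m$response, form = m$form,
        fit = nm, n_points = m$n_points, r_squared = m$r_squared,
        slope = m$slope,
        coefficients = paste(format(m$coefficients, digits = 8),
                             collapse = ","))
    }
    for (nm in c("T_parallel_linear", "T_crossed_linear", "ratio_linear")) {
      ld <- limit_of_detection(wl_models[[nm]], convention)
      lod_rows[[length(lod_rows) + 1]] <- data.frame(
        wavelength_nm = wl_act, channel = ld$response,
        convention = ld$convention, slope_m = ld$slope_m,
        intercept_sd_s = ld$intercept_sd_s,
        lod_g_per_mL = ld$lod_concentration)
    }
  })
  calibrations <- do.call(rbind, cal_rows)
  lod_table <- do.call(rbind, lod_rows)
  note("calibration: %d wavelengths x %d fits", length(wavelengths), 5L)

  sensitivity <- stage("sensitivity", {
    per_channel <- function(fit_name) wavelength_sensitivity_scan(
      lapply(models, function(m) m[[fit_name]]), convention)
    list(T_parallel = per_channel("T_parallel_linear"),
         T_crossed = per_channel("T_crossed_linear"),
         ratio = per_channel("ratio_linear"))
  })

  predictions <- NULL
  if (!is.null(config$unknowns)) {
    predictions <- stage("prediction", {
      do.call(rbind, lapply(seq_along(config$unknowns), function(k) {
        u <- config$unknowns[[k]]
        ref <- sim$references[[1]]
        red <- reduce_transmittance(u$parallel, u$crossed,
                                    ref$parallel, ref$crossed)
        rows <- lapply(names(models), function(wl_key) {
          m <- models[[wl_key]]$T_parallel_cubic
          i <- nearest_index(red$wavelength_nm, m$wavelength_nm)
          pred <- tryCatch(
            predict_concentration(m, red$T_parallel[i]),
            error = function(e) NULL)
          if (is.null(pred)) return(NULL)
          data.frame(unknown = k, wavelength_nm = m$wavelength_nm,
                     response = red$T_parallel[i],
                     concentration_g_per_mL = pred$concentration)
        })
        do.call(rbind, rows)
      }))
    })
    note("prediction: %d unknown sample(s)", length(config$unknowns))
  }

  report <- structure(
    list(calibrations = calibrations, models = models,
         lod_table = lod_table, sensitivity = sensitivity,
         predictions = predictions, reduced = reduced,
         wavelengths = wavelengths, convention = convention,
         log = log_lines),
    class = "quantitation_report")

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    wt <- function(df, f) utils::write.table(
      df, file.path(config$output_dir, f), sep = "\t", quote = FALSE,
      row.names = FALSE)
    wt(calibrations, "calibrations.tsv")
    wt(lod_table, "lod.tsv")
    wt(do.call(rbind, lapply(names(sensitivity), function(ch)
      cbind(channel = ch, sensitivity[[ch]]))), "sensitivity.tsv")
    if (!is.null(predictions)) wt(predictions, "predictions.tsv")
    writeLines(log_lines, file.path(config$output_dir, "run.log"))
  }
  report
}

#' @export
print.quantitation_report <- function(x, ...) {
  cat(sprintf("<quantitation_report> %d wavelengths, LOD convention %s\n",
              length(x$wavelengths), x$convention))
  cat("LOD (g/mL) by wavelength and channel:\n")
  print(utils::head(x$lod_table, 12))
  invisible(x)
}

#' Render the report's standard figures
#'
#' Writes three figure files (PNG): mean reduced-transmittance dose
#' curves with their cubic fits, the per-wavelength ratio-vs-log10c lines
#' with R-squared annotations, and the LOD-vs-wavelength summary.
#'
#' @param report A `quantitation_report`.
#' @param dir Output directory.
#' @return Character vector of the files written, invisibly.
#' @export
plot_report <- function(report, dir) {
  stopifnot(inherits(report, "quantitation_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  fig <- function(name, expr) {
    path <- file.path(dir, name)
    grDevices::png(path, width = 900, height = 600)
    on.exit(grDevices::dev.off(), add = TRUE)
    expr
    files <<- c(files, path)
  }
  concs <- vapply(report$reduced, function(r) attr(r, "concentration"),
                  numeric(1))
  x <- log10(concs)

  fig("calibration_curves.png", {
    graphics::par(mfrow = c(1, 2))
    for (fit_name in c("T_parallel_cubic", "T_crossed_cubic")) {
      first <- TRUE
      cols <- grDevices::hcl.colors(length(report$models), "viridis")
      for (j in seq_along(report$models)) {
        m <- report$models[[j]][[fit_name]]
        if (first) {
          graphics::plot(m$data$x, m$data$y, col = cols[j], pch = 16,
                         xlab = "log10 concentration (g/mL)",
                         ylab = m$response,
                         main = sprintf("%s cubic calibrations", m$response),
                         ylim = range(vapply(report$models, function(mm)
                           range(mm[[fit_name]]$data$y), numeric(2))))
          first <- FALSE
        } else graphics::points(m$data$x, m$data$y, col = cols[j], pch = 16)
        xs <- seq(m$fit_range[1], m$fit_range[2], length.out = 100)
        graphics::lines(xs, evaluate_calibration(m, xs), col = cols[j])
      }
    }
  })

  fig("ratio_lines.png", {
    cols <- grDevices::hcl.colors(length(report$models), "viridis")
    first <- TRUE
    for (j in seq_along(report$models)) {
      m <- report$models[[j]]$ratio_linear
      if (first) {
        graphics::plot(m$data$x, m$data$y, col = cols[j], pch = 16,
                       xlab = "log10 concentration (g/mL)",
                       ylab = "T_parallel / T_crossed",
                       main = "Ratio calibrations by wavelength")
        first <- FALSE
      } else graphics::points(m$data$x, m$data$y, col = cols[j], pch = 16)
      graphics::abline(m$coefficients[1], m$coefficients[2], col = cols[j])
      graphics::text(m$data$x[1], m$data$y[1],
                     sprintf("%g nm R2=%.3f", m$wavelength_nm, m$r_squared),
                     pos = 4, cex = 0.7, col = cols[j])
    }
  })

  fig("lod_by_wavelength.png", {
    lt <- report$lod_table
    chans <- unique(lt$channel)
    cols <- seq_along(chans)
    graphics::plot(NULL, xlim = range(lt$wavelength_nm),
                   ylim = range(log10(lt$lod_g_per_mL)),
                   xlab = "wavelength (nm)", ylab = "log10 LOD (g/mL)",
                   main = sprintf("LOD by wavelength (%s)", report$convention))
    for (k in seq_along(chans)) {
      sub <- lt[lt$channel == chans[k], ]
      graphics::lines(sub$wavelength_nm, log10(sub$lod_g_per_mL),
                      col = cols[k], type = "b", pch = 16)
    }
    graphics::legend("topleft", legend = chans, col = cols, lty = 1, pch = 16)
  })
  invisible(files)
}
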