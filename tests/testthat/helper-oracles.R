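# Independent oracles used across test files. These deliberately avoid the
# package's own code paths.

# Polynomial OLS via explicit normal equations, with intercept standard error.
ols_oracle <- function(x, y, degree = 1) {
  X <- outer(x, 0:degree, `^`)
  d <- sqrt(colSums(X^2))          # column scaling keeps X'X well conditioned
  Xs <- sweep(X, 2, d, "/")
  XtXi_s <- solve(crossprod(Xs))
  beta <- drop(XtXi_s %*% crossprod(Xs, y)) / d
  XtXi <- sweep(sweep(XtXi_s, 1, d, "/"), 2, d, "/")
  res <- y - X %*% beta
  sigma2 <- sum(res^2) / (length(y) - ncol(X))
  list(coefficients = beta,
       se = sqrt(sigma2 * diag(XtXi)),
       sigma = sqrt(sigma2))
}

# Constant-index dispersion (Cauchy B = 0), handy for hand-checkable optics.
const_dispersion <- function(n_par, n_perp, range = c(400, 800)) {
  dispersion_model(c(n_par, 0), c(n_perp, 0), range)
}

# Noisy parallel/crossed pair simulated at a given azimuth (degrees).
noisy_pair_at <- function(azimuth_deg, grid, mult_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cell <- cell_optics(azimuth_deg = azimuth_deg)
  sp <- simulate_spectrum(cell, grid, "parallel", "with-analyte")
  sc <- simulate_spectrum(cell, grid, "crossed", "with-analyte")
  if (mult_sd > 0) {
    sp$transmittance <- sp$transmittance * (1 + stats::rnorm(length(grid), 0, mult_sd))
    sc$transmittance <- sc$transmittance * (1 + stats::rnorm(length(grid), 0, mult_sd))
  }
  list(parallel = sp, crossed = sc)
}

# Full pipeline azimuth recovery: simulate an experiment, reduce each
# concentration, estimate phi per replicate, refit the logistic link.
recover_link <- function(seed, noise = noise_model(0.02, 0.002, seed = seed)) {
  cfg <- synthetic_experiment(noise = noise)
  sim <- simulate_experiment(cfg)
  phis <- vapply(sim$series, function(s) {
    mean(vapply(seq_along(s$replicates), function(r) {
      ref <- sim$references[[r]]
      red <- reduce_transmittance(s$replicates[[r]]$parallel,
                                  s$replicates[[r]]$crossed,
                                  ref$parallel, ref$crossed,
                                  concentration = s$concentration)
      sp <- spectrum(red$wavelength_nm, red$T_parallel, "parallel")
      sc <- spectrum(red$wavelength_nm, red$T_crossed, "crossed")
      estimate_phi(sp, sc, cfg$cell)$phi_rad
    }, numeric(1)))
  }, numeric(1))
  list(fit = fit_dose_response(vapply(sim$series, `[[`, numeric(1),
                                      "concentration"), phis),
       truth = cfg$link)
}
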