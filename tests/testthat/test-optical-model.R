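test_that("effective index collapses correctly at the pretilt extremes", {
  disp <- const_dispersion(1.50, 1.60)
  expect_identical(effective_index(disp, pi / 2, 550), 1.60)
  expect_identical(effective_index(disp, 0, 550), 1.50)
  # vertical alignment: birefringence vanishes exactly
  expect_identical(birefringence(disp, 550, theta = pi / 2), 0)
})

test_that("effective index matches an independently written closed form", {
  disp <- const_dispersion(1.50, 1.60)
  # oracle written as the reciprocal-quadrature form, not the package's ratio
  oracle <- function(n_par, n_perp, theta)
    1 / sqrt(sin(theta)^2 / n_perp^2 + cos(theta)^2 / n_par^2)
  for (theta in c(pi / 4, 0.1, 1.2)) {
    expect_equal(effective_index(disp, theta, 550),
                 oracle(1.50, 1.60, theta), tolerance = 1e-14)
  }
})

test_that("out-of-range wavelengths raise a domain error naming the range", {
  disp <- const_dispersion(1.50, 1.60, range = c(400, 800))
  expect_error(effective_index(disp, 0, 900), "valid range.*400.*800")
  expect_error(phase_retardation(cell_optics(dispersion = disp), 350),
               "valid range")
})

test_that("dispersion construction rejects sign-flipping or unphysical indices", {
  expect_error(dispersion_model(c(1.5, 0), c(1.5, -1e5), c(400, 800)),
               "finite and > 1|sign")
  # n_par - n_perp changes sign across the range
  expect_error(dispersion_model(c(1.55, -10000), c(1.53, 0), c(400, 800)),
               "changes sign")
})

test_that("phase retardation follows 2*pi*d*dn/lambda with its sign", {
  disp <- const_dispersion(1.518, 1.500)  # dn = +0.018
  cell <- cell_optics(gap_nm = 15000, dispersion = disp)
  expect_equal(phase_retardation(cell, 450), 2 * pi * 15000 * 0.018 / 450,
               tolerance = 1e-12)
  neg <- cell_optics(gap_nm = 15000, dispersion = const_dispersion(1.500, 1.518))
  expect_equal(phase_retardation(neg, 450), -2 * pi * 15000 * 0.018 / 450,
               tolerance = 1e-12)
  vert <- cell_optics(gap_nm = 15000, pretilt_deg = 90, dispersion = disp)
  expect_equal(phase_retardation(vert, 450), 0)
})

test_that("single-retarder transmittances reproduce the printed special cases", {
  for (delta in seq(0, 2 * pi, length.out = 9)) {
    expect_identical(transmittance_parallel(0, delta), 1)
    expect_identical(transmittance_crossed(0, delta), 0)
  }
  # half-wave condition at 45 degrees: full switching
  expect_equal(transmittance_parallel(pi / 4, pi), 0, tolerance = 1e-12)
  expect_equal(transmittance_crossed(pi / 4, pi), 1, tolerance = 1e-12)
  # hand arithmetic on the closed form
  expect_equal(transmittance_parallel(pi / 8, pi / 2), 0.75, tolerance = 1e-14)
  expect_equal(transmittance_crossed(pi / 8, pi / 2), 0.25, tolerance = 1e-14)
})

test_that("transmittance pair conserves energy and respects its symmetries", {
  set.seed(101)
  phi <- runif(2000, -2 * pi, 2 * pi)
  delta <- runif(2000, -20, 20)
  ipar <- transmittance_parallel(phi, delta)
  iperp <- transmittance_crossed(phi, delta)
  expect_true(all(abs(ipar + iperp - 1) < 1e-12))
  expect_true(all(ipar >= 0 & ipar <= 1))
  expect_true(all(iperp >= 0 & iperp <= 1))
  # pi/2-periodic in phi, even in delta
  expect_equal(transmittance_crossed(phi + pi / 2, delta), iperp,
               tolerance = 1e-12)
  expect_equal(transmittance_parallel(phi, -delta), ipar, tolerance = 1e-12)
  # strict monotonicity of the crossed channel in phi on [0, pi/4]
  phis <- seq(0, pi / 4, length.out = 50)
  vals <- transmittance_crossed(phis, 2.5)
  expect_true(all(diff(vals) > 0))
})

test_that("simulated spectra vectorize the scalar formulas over the grid", {
  grid <- seq(400, 800, by = 2)
  ref <- simulate_spectrum(cell_optics(azimuth_deg = 0), grid, "parallel")
  expect_true(all(ref$transmittance == 1))
  cell <- cell_optics(azimuth_deg = 27)
  sp <- simulate_spectrum(cell, grid, "parallel")
  sc <- simulate_spectrum(cell, grid, "crossed")
  expect_true(all(abs(sp$transmittance + sc$transmittance - 1) < 1e-14))
  expect_error(simulate_spectrum(cell, numeric(0), "parallel"), "empty")
  # flipping the sign of the birefringence leaves both spectra unchanged
  flipped <- cell_optics(azimuth_deg = 27,
                         dispersion = dispersion_model(c(1.530, 4000),
                                                       c(1.517, 3000)))
  expect_equal(simulate_spectrum(flipped, grid, "parallel")$transmittance,
               sp$transmittance, tolerance = 1e-12)
})

test_that("a uniform Jones stack collapses to the single-retarder formulas", {
  set.seed(202)
  for (k in 1:25) {
    phi <- runif(1, 0, pi / 4)
    total <- runif(1, 0, 12)
    n_slab <- sample(1:40, 1)
    deltas <- rep(total / n_slab, n_slab)
    expect_equal(
      jones_stack_transmittance(rep(phi, n_slab), deltas, "parallel"),
      transmittance_parallel(phi, total), tolerance = 1e-10)
    expect_equal(
      jones_stack_transmittance(rep(phi, n_slab), deltas, "crossed"),
      transmittance_crossed(phi, total), tolerance = 1e-10)
  }
  expect_equal(jones_stack_transmittance(0, 1.3, "crossed"), 0,
               tolerance = 1e-14)
  expect_error(jones_stack_transmittance(c(0, 1), 1, "parallel"),
               "equal nonzero length")
})

test_that("twisted-stack transmittance converges under slab refinement", {
  total_delta <- 5
  # midpoint discretization of the continuous twist profile (second-order
  # accurate in the slab count)
  twist <- function(n) {
    list(phis = (seq_len(n) - 0.5) / n * 30 * pi / 180,
         deltas = rep(total_delta / n, n))
  }
  t64 <- twist(64); t128 <- twist(128)
  for (scheme in c("parallel", "crossed")) {
    expect_equal(
      jones_stack_transmittance(t64$phis, t64$deltas, scheme),
      jones_stack_transmittance(t128$phis, t128$deltas, scheme),
      tolerance = 1e-4)
  }
})

test_that("azimuth estimation recovers the generating angle on its branch", {
  grid <- seq(400, 800, by = 1)
  ref_cell <- cell_optics()
  # noiseless recovery across the identifiable branch
  for (phi_deg in c(0, 5, 20, 37, 44)) {
    pair <- noisy_pair_at(phi_deg, grid)
    est <- estimate_phi(pair$parallel, pair$crossed, ref_cell)
    expect_equal(est$phi_rad, phi_deg * pi / 180, tolerance = 1e-6)
  }
  # 1% multiplicative noise, 400 wavelengths: within one degree
  pair <- noisy_pair_at(20, seq(400, 799, length.out = 400),
                        mult_sd = 0.01, seed = 42)
  expect_lt(abs(estimate_phi(pair$parallel, pair$crossed, ref_cell)$phi_deg - 20), 1)
  # azimuths above 45 degrees alias onto the principal branch
  pair70 <- noisy_pair_at(70, grid)
  expect_equal(estimate_phi(pair70$parallel, pair70$crossed, ref_cell)$phi_deg,
               20, tolerance = 1e-6)
})

test_that("azimuth estimation fails loudly when retardation nulls everywhere", {
  # vertical pretilt: delta = 0 at every wavelength, sin^2(delta/2) = 0
  vert <- cell_optics(pretilt_deg = 90)
  grid <- seq(400, 800, by = 10)
  pair <- noisy_pair_at(20, grid)
  expect_error(estimate_phi(pair$parallel, pair$crossed, vert),
               "unidentifiable")
})
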