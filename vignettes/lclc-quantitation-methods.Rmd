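---
title: "Methods: polarized-transmittance quantitation with chromonic liquid-crystal biosensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polarized-transmittance quantitation with chromonic liquid-crystal biosensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lclcquant)
```

## The sensing principle

The biosensor this package analyzes is a thin cell of planar-aligned
lyotropic chromonic liquid crystal (nematic disodium cromoglycate, DSCG, in
water) assembled on a rubbed polyimide substrate carrying immobilized
biomolecules. In the analyte-free ground state the director lies along the
rubbing direction, which is set parallel to the transmission axis of the
analyzer. Biomolecules at the LC-glass interface disturb that alignment:
because the twist elastic constant of a chromonic nematic is much smaller
than splay or bend, the disturbance is predominantly azimuthal, an in-plane
rotation of the director by an angle $\phi$ that grows with the amount of
captured analyte.

Reading the cell between two polarizers turns $\phi$ into light. For a
uniform director at azimuth $\phi$ with phase retardation $\delta$, Jones
calculus gives

$$I_\parallel = 1 - \sin^2(2\phi)\,\sin^2(\delta/2), \qquad
  I_\perp = \sin^2(2\phi)\,\sin^2(\delta/2),$$

for parallel and crossed polarizers respectively. The retardation is
$\delta = 2\pi d \Delta n / \lambda$ with cell gap $d$, wavelength
$\lambda$, and birefringence $\Delta n = n_{\mathrm{eff}} - n_\perp$, where

$$n_{\mathrm{eff}} = \frac{n_\perp n_\parallel}
  {\sqrt{n_\parallel^2 \sin^2\theta + n_\perp^2 \cos^2\theta}}$$

for pretilt $\theta$ ($\theta = 0$: planar, maximal birefringence;
$\theta = \pi/2$: vertical, $\Delta n = 0$). The two channels sum to one
identically, both are even in $\delta$, and both depend on the sign of
$\Delta n$ only through $\sin^2(\delta/2)$ — which matters because DSCG is
optically negative.

### The twisted region and the uniform-director approximation

Above an analyte spot the director is twisted: disturbed near the
functionalized substrate, planar at the far, protein-free substrate. No
closed-form transmittance exists for that profile, and the package follows
the single-retarder formulas above as its primary forward model, reading
$\phi$ as the effective in-plane angle of the average molecular axis. As a
numerical check (and an optional forward model) the package also provides
`jones_stack_transmittance()`, a multi-slab 2x2 complex Jones-matrix
product that can represent any discretized twist profile. A uniform stack
collapses to the closed form at the $10^{-10}$ level, which the test suite
verifies over randomized stacks; a linearly twisted profile discretized at
slab midpoints converges with slab count at second order.

### Azimuth estimation

`estimate_phi()` inverts the model: at each wavelength
$\sin^2(2\phi) = I_\perp / \sin^2(\delta/2)$, and pooling the crossed
channel with the complement of the parallel channel gives a linear
least-squares problem for $a = \sin^2(2\phi)$ across the spectrum.
Wavelengths with $\sin^2(\delta/2) < 10^{-3}$ are excluded — near a
half-wave null the azimuth carries no signal — and if every wavelength sits
below the floor the estimator refuses rather than guessing. Because
$\sin^2(2\phi)$ is symmetric about $45^\circ$, estimates are reported on
the principal branch $[0^\circ, 45^\circ]$ only; an azimuth of $70^\circ$
aliases to $20^\circ$ and the package documents, rather than resolves, that
ambiguity.

## Reduced transmittance

Raw with-analyte spectra $S_\parallel, S_\perp$ are normalized against the
analyte-free references $T_\parallel^{w/o}, T_\perp^{w/o}$ measured on the
same optics:

$$T_\parallel = \frac{S_\parallel - T_\perp^{w/o}}
   {T_\parallel^{w/o} - T_\perp^{w/o}}, \qquad
  T_\perp = \frac{S_\perp - T_\perp^{w/o}}
   {T_\parallel^{w/o} - T_\perp^{w/o}},$$

so the blank maps to $(1, 0)$ and background or false-positive signal
common to both conditions cancels. Three deliberate choices:

* **Exact grid match.** All four spectra must share one wavelength grid;
  `resample_spectrum()` exists but must be invoked explicitly, so
  instrument drift between acquisitions is never hidden by silent
  interpolation.
* **No clipping.** Under noise, reduced values legitimately stray slightly
  outside $[0, 1]$; the reducer preserves them. A degenerate reference pair
  ($|T_\parallel^{w/o} - T_\perp^{w/o}| < 10^{-6}$ at any wavelength) is
  an error, not a warning.
* **Ratio guard.** $T_\parallel / T_\perp$ is reported as undefined (`NA`)
  where $|T_\perp| < 10^{-9}$: at blank-like conditions the ratio
  diverges, which is why ratio calibrations use only analyte-bearing
  concentrations.

Replicates are reduced per wavelength first and averaged afterwards
(`aggregate_replicates()`, sample standard deviation with $n-1$
denominator). The alternative — averaging raw spectra before reduction —
would entangle replicate-specific reference cells; reducing each replicate
against its own reference matches how the cells are actually measured.
A single-replicate aggregate is allowed but flagged, with sd 0 by
convention.

## Calibration and the limit of detection

Calibrations regress a response channel on $x = \log_{10}(c\,/\,\mathrm{g\,mL^{-1}})$.
Two forms cover the two regimes seen in practice: a **cubic** polynomial
for the full dilution series, whose S-shaped saturation at both
concentration extremes a straight line cannot follow, and a **linear** fit
for the narrow low-concentration range and for the
$T_\parallel/T_\perp$ ratio, which is close to linear in $\log_{10} c$
across the series. Goodness of fit is the plain
$R^2 = 1 - SS_{res}/SS_{tot}$ for both forms (no adjustment), fits are
unweighted, and true blanks ($c = 0$) are inadmissible — the blank enters
through the reference spectra, not the regression.

The limit of detection uses the $3s/m$ rule: three times the standard
error of the fitted intercept over the slope magnitude. With a
$\log_{10}$ abscissa that quotient carries log-concentration units, so the
package implements two explicit conventions behind a mandatory argument
and never defaults silently:

* `"abscissa-domain"`: $\mathrm{LOD} = 10^{\,3s/|m|}$ g/mL, taken against
  a 1 g/mL dimensional anchor. Invariant under affine rescaling of the
  response. Note that the intercept of a regression whose abscissa spans,
  say, $-12$ to $-10$ sits ten decades outside the data, so $s$ — and the
  resulting LOD — is dominated by extrapolation; the quantity is
  well-defined but should be read as a convention, not a concentration the
  assay could measure.
* `"signal-domain"`: the calibration points are re-regressed against
  linear concentration over the same range and $3s/|m|$ is taken directly
  in g/mL. This lands on the scale of the fitted concentrations and is the
  convention the worked examples use.

By default the linear range for LOD regressions is the three lowest
concentrations of the series, a user-adjustable choice
(`linear_range_n`) reflecting that linearity can only be ascertained over
a narrow sub-range of an S-shaped dose curve.

Inverse prediction (`predict_concentration()`) solves the fitted
polynomial inside the fit range and exponentiates the unique in-range
root. A cubic that is non-monotone over its range warns at fit time, and
an inversion that finds several in-range roots fails loudly listing all of
them — guessing a branch would silently corrupt downstream quantitation.
Responses outside the fitted response range are refused. A first-order
interval is propagated from the response standard deviation through the
local slope.

`wavelength_sensitivity_scan()` tabulates $|m|$ and LOD across
wavelengths. For a normally dispersive mesogen $|\Delta n|$, and with it
$\delta$ and the dose-response amplitude $\sin^2(\delta/2)$, grows toward
the blue, so the scan is expected to flag the shortest examined wavelength
(450 nm in the default set) as most sensitive; ties are all flagged.

## Cell-gap interferometry

The empty cell is a low-finesse air cavity: two-beam interference puts
transmittance maxima at $\lambda = 2nd/m$. `detect_fringes()` finds local
maxima by topographic prominence (not absolute height), which makes the
fringe set invariant to the smooth lamp/detector envelope, and refines
each peak position with a three-point parabola for sub-grid accuracy.
`estimate_gap()` counts the $N$ fringe intervals between the first and
last maxima:

$$d = \frac{N\,\lambda_1 \lambda_N}{2 n (\lambda_N - \lambda_1)}.$$

Only interval counts are used — no absolute fringe order is ever assigned
— and the uncertainty is propagated from the per-peak wavelength
resolution (default: half the grid step). Maxima are used rather than
minima, and the medium index defaults to 1 because the gap is measured on
the empty cell before filling. Wedge-shaped gaps and filled-cell retrieval
through a dispersive medium are out of scope.

## The synthetic-experiment generator

The generator exists so every downstream stage is testable without an
instrument. It emulates the measurement design of the assay it models: a
dilution series of $10^{-12}$ to $10^{-5}$ g/mL by decades, $n = 3$
replicates, spectra on 400-800 nm, acquired in both polarizer schemes with
analyte-free reference pairs.

Its parts, and what is and is not physical about them:

* **Dispersion.** Two-term Cauchy forms
  $n_\parallel = 1.517 + 3000/\lambda^2$,
  $n_\perp = 1.530 + 4000/\lambda^2$ ($\lambda$ in nm). These are package
  constants, not measured coefficients; they give a negative birefringence
  of magnitude $\approx 0.019$ at 400 nm falling to $\approx 0.015$ at
  800 nm, the small, normally dispersive, optically negative behaviour
  expected of nematic DSCG.
* **Dose-response link.** $\phi(c) = \phi_{max} / (1 +
  10^{-h(\log_{10} c - \log_{10} c_{50})})$, $\phi(0) = 0$, with defaults
  $\phi_{max} = 40^\circ$, $c_{50} = 10^{-8.5}$ g/mL, $h = 0.25$. The true
  concentration-to-azimuth map of these cells is unknown (only
  transmittance is observed), so this logistic is a stand-in with the
  right qualitative features: a blank-like plateau at trace
  concentrations, saturation at high load, and a curvature gentle enough
  that a cubic in $\log_{10} c$ describes the noiseless dose curve
  essentially exactly, which is the regime in which cubic calibration is
  the appropriate tool. $\phi_{max}$ is capped at $45^\circ$ to stay on
  the identifiable branch. No claim of physical fidelity is made for the
  link's form or parameter values.
* **Noise.** Each transmittance value becomes
  $t(1 + \varepsilon_{mult}) + \varepsilon_{add}$ with independent
  Gaussian draws, defaults 2% multiplicative and 0.002 additive — a
  replicate scatter of roughly 0.02 on near-unity signals, typical of
  fiber-optic spectrometer repeats. All draws come from one seeded stream
  in a documented order (references first, then concentrations ascending,
  parallel before crossed, multiplicative before additive), so the seed
  fully determines the file tree that `generate_experiment()` writes.

What the generator does **not** emulate: antibody-antigen binding
kinetics, spatial heterogeneity of the sensing spot, polarizer extinction
limits, reflection losses, scattering from LC texture defects, wavelength
calibration drift, or correlated (1/f-like) instrument noise. Passing
end-to-end tests on synthetic data therefore demonstrates the correctness
and statistical behaviour of the analysis chain under the model's
assumptions — not the instrument-level performance of a physical assay.

## Numerical choices and test problem sizes

* Angles are radians internally, degrees at every user-facing interface.
* $\sin^2(\delta/2)$ admissibility floor for azimuth estimation:
  $10^{-3}$; degenerate-reference floor: $10^{-6}$; ratio-definedness
  floor: $10^{-9}$.
* OLS is delegated to `stats::lm`; the test suite checks slope, intercept
  and intercept standard error against an independently coded,
  column-scaled normal-equations solver at $10^{-10}$.
* The property suites run at sizes chosen to exercise the asymptotics
  while staying desk-scale: $10^5$ random $(\phi, \delta)$ pairs for the
  conservation identity, $10^3$ random cells for the Jones-stack
  equivalence, 50-seed batches for link recovery, 2048-sample spectra for
  gap retrieval, and 1 nm grids (401 points) for full synthetic
  experiments.
* The dose signal's monotonicity and calibration sign structure are
  asserted across seed batches, reflecting that these are distributional,
  not per-realization, properties.

## Known limitations

* The uniform-director reading of $\phi$ is an effective-parameter
  approximation to a genuinely twisted cell; the slab-stack oracle bounds
  the discretization error of a *given* profile but cannot say which
  profile a real cell adopts.
* The abscissa-domain LOD convention inherits the extrapolation
  sensitivity discussed above; comparisons between instruments should fix
  one convention and one linear range.
* Azimuths above $45^\circ$ are indistinguishable from their reflection;
  a dose so high that $\phi$ crosses $45^\circ$ would fold the dose curve.
* Surface-tension and elastic-constant arguments for *why* the director
  deviates azimuthally are qualitative background; nothing in the package
  computes them.
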