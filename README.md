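# lclcquant

Quantitation tools for label-free biosensors that read out a planar-aligned
lyotropic chromonic liquid-crystal (LCLC) cell — nematic disodium
cromoglycate (DSCG) on rubbed polyimide — by visible transmission
spectrometry between parallel or crossed polarizers. Biomolecules captured
at the LC–glass interface twist the director azimuthally; the package turns
the resulting wavelength-dependent transmittance change into calibrated
analyte concentrations, for people building or analyzing such assays
(model protein standards like BSA, or antibody/biomarker pairs like
anti-CA125/CA125).

## The model

For a uniform director at azimuth φ from the analyzer axis, with phase
retardation δ = 2πdΔn/λ (cell gap d, birefringence Δn = n_eff − n⊥):

    I∥ = 1 − sin²(2φ)·sin²(δ/2)        parallel polarizers
    I⊥ =     sin²(2φ)·sin²(δ/2)        crossed polarizers

    n_eff = n⊥·n∥ / √(n∥²·sin²θ + n⊥²·cos²θ)     (pretilt θ)

Raw with-analyte spectra (S∥, S⊥) are normalized against analyte-free
references so the blank maps to (1, 0):

    T∥ = (S∥ − T⊥ʷᐟᵒ) / (T∥ʷᐟᵒ − T⊥ʷᐟᵒ)
    T⊥ = (S⊥ − T⊥ʷᐟᵒ) / (T∥ʷᐟᵒ − T⊥ʷᐟᵒ)

Calibration curves regress T∥, T⊥ (cubic in log₁₀ c over the full dilution
series; linear over a narrow range) or the ratio T∥/T⊥ (linear) on log₁₀
concentration, and the limit of detection is LOD = 3s/m — three times the
intercept's standard error over the slope, under an explicitly chosen
convention (see the methods vignette). The empty-cell gap is estimated from
thin-film interference fringes by interval counting,
d = N·λ₁·λ_N / (2n(λ_N − λ₁)).

A multi-slab Jones-matrix model (`jones_stack_transmittance()`) backs the
closed-form optics as an independent oracle, and a synthetic-experiment
generator (`synthetic_experiment()`, `generate_experiment()`) produces
complete noisy dilution-series data sets for end-to-end testing.

## Worked example

Run the full workflow on a synthetic eight-decade dilution series
(10⁻¹²–10⁻⁵ g/mL, 3 replicates, 400–800 nm, 2% noise):

```r
library(lclcquant)
cfg <- list(synthetic = list(seed = 11), lod_convention = "signal-domain")
rep <- run_quantitation(cfg)
subset(rep$lod_table, wavelength_nm == 450)
#>  wavelength_nm    channel    convention     slope_m intercept_sd_s lod_g_per_mL
#>            450 T_parallel signal-domain -1084637731     0.00814988 2.254176e-11
#>            450  T_crossed signal-domain  1117518445     0.01380652 3.706387e-11
#>            450      ratio signal-domain     -915507     4.65116796 1.524129e-05

subset(rep$calibrations, wavelength_nm == 450 & form == "cubic")[,
       c("channel", "n_points", "r_squared")]
#>     channel n_points r_squared
#>  T_parallel        8 0.9997699
#>   T_crossed        8 0.9997311
```

The T∥ channel falls and the T⊥ channel rises with concentration (negative
and positive slopes), the cubic calibrations describe the S-shaped dose
curves with R² > 0.999, and the signal-domain 3s/m LODs land in the
10⁻¹¹–10⁻¹⁰ g/mL range at 450 nm. The divergent ratio LOD reflects that
the ratio regression spans the full series rather than the trace range.

Cell-gap interferometry on a synthetic 15 µm empty cell:

```r
s <- generate_empty_cell_spectrum(15000, seq(400, 800, length.out = 2048))
est <- estimate_gap(detect_fringes(s))
#> gap: 15000.0 +/- 7.7 nm from 36 fringe intervals
```

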