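Package: lclcquant
Title: Quantitation Pipeline for Polarized-Transmittance Liquid-Crystal Biosensors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward optical model and quantitation workflow for label-free
    biosensors built on planar-aligned lyotropic chromonic liquid crystal
    (LCLC) cells read out by transmission spectrometry between parallel or
    crossed polarizers. Implements the Jones-calculus transmittance of a
    birefringent cell, reduced-transmittance normalization against
    analyte-free references, calibration-curve fitting (cubic polynomial in
    log10 concentration, linear ratio fits), the 3s/m limit of detection
    under both abscissa-domain and signal-domain conventions, inverse
    concentration prediction, interferometric cell-gap estimation from
    empty-cell fringes, and a synthetic-experiment generator that emulates
    dilution series of noisy replicate spectra for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    minpack.lm,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
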