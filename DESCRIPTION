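Package: viband
Title: Spectral Band Optimization for Vegetation-Index Pigment Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how leaf chlorophyll and carotenoid estimation
    from two-band vegetation indices depends on the spectral channels used to
    compute them. Simulates sensor channels as Gaussian transmission functions
    (central wavelength and full width at half maximum), computes seven common
    two-band vegetation indices over an exhaustive wavelength-pair grid,
    calibrates exponential pigment~index regressions, selects optimal channel
    configurations by coefficient of determination, and quantifies sensitivity
    of the calibration to wavelength shifts, bandwidth changes and index
    formula substitution. Includes a synthetic leaf-reflectance generator with
    pigment-dependent absorption features and the spectrophotometric reference
    equations linking extract optical densities to pigment concentrations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    MASS,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
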