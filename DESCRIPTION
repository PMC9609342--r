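Package: ramanqc
Title: Chemometric Calibration Pipeline for Process Raman Spectroscopy
Version: 0.1.0
Authors@R:
    person("ramanqc", "maintainers", email = "ramanqc@example.org",
           role = c("aut", "cre"))
Description: Quantitative calibration of process Raman spectra for botanical
    extract manufacturing: Savitzky-Golay smoothing and min-max scaling,
    Mahalanobis-distance outlier screening in principal-component score
    space, Kennard-Stone calibration/validation splitting, wavelength
    selection by competitive adaptive reweighted sampling (CARS) with
    uninformative variable elimination (UVE), the successive projections
    algorithm (SPA) and synergy-interval PLS (siPLS) as comparators, and
    calibration engines (PLS regression, epsilon-SVR, and a 1-D
    convolutional network) evaluated by RMSEC/RMSECV/RMSEP and their
    coefficients of determination. Includes a synthetic extraction-process
    data generator with known ground truth so every pipeline stage is
    testable without proprietary factory data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    quadprog
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
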