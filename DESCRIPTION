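Package: specbase
Title: Baseline Correction for Raman Spectra by Joint Subspace Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Removes fluorescence baselines from Raman spectra by modelling
    the measured spectrum as a linear combination of reference analyte
    spectra, a background basis, and broad Gaussian vectors spanning smooth
    baselines, estimated jointly by least squares. Also provides five
    classical baseline correctors (iterative median filter, rolling circle
    filter, and the penalized least-squares family ALS, AirPLS and ArPLS),
    the root-mean-square modelling error metric, the adaptive subspace
    detector with ROC evaluation, and a seeded synthetic-spectrum generator
    for benchmarking correctors under controlled conditions.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
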