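Package: webaudiometry
Title: Simulation and Measurement-Error Analysis of Web-Based Pure-Tone Audiometry
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to study the validity of self-administered web-based
    pure-tone audiometry against clinical audiometry. Simulates a
    three-series study design (clinical audiometer, supervised self-test on
    a calibrated station, unsupervised self-test at home) from an explicit
    additive error model over latent audiograms; provides behavioral models
    of the clinical ascending method, the self-adjustment task, and the
    paired-tone reference-person calibration with A-weighting extrapolation;
    computes between-series agreement statistics (mean difference, SD of
    differences, Pearson correlation with Fisher intervals, Deming
    errors-in-variables regression with jackknife intervals); decomposes the
    between-series difference SDs into procedure, calibration, frequency
    nonlinearity, gain, noise, population and calibration-task components by
    variance subtraction; and scores a noise-induced hearing-loss screening
    criterion with sensitivity and specificity.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
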