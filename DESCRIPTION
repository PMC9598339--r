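Package: uroraman
Title: Chemometric Analysis of Urine Raman Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dispersive Raman spectroscopy of urine aimed at
    metabolic screening. Implements the standard spectral pre-processing
    chain (automated cosmic-ray despiking, iterative fifth-order polynomial
    fluorescence baseline removal, water-band area normalization and
    signal-to-noise quality filtering), multivariate calibration and
    classification (PCA, NIPALS partial least squares regression with
    leave-one-out cross-validation, PLS-DA and linear discriminant
    analysis), evaluation utilities (confusion matrices, sensitivity,
    specificity and accuracy, reference-range flagging, concentration unit
    conversion), and a seeded synthetic cohort generator that produces
    urine Raman spectra with known biomarker ground truth for end-to-end
    validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    jsonlite,
    optparse
Config/testthat/edition: 3
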