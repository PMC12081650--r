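Package: nirscal
Title: Multi-Trait NIRS Calibration with Modified PLS and Chemometric Validation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A chemometrics toolkit for building and validating near-infrared
    reflectance spectroscopy (NIRS) calibrations of grain nutritional traits.
    Implements standard normal variate and detrend (SNV-DT) scatter correction,
    WinISI-style gap-segment derivative math treatments, Mahalanobis GH/NH
    spectral outlier screening, rank-ordered calibration/validation splitting,
    modified partial least squares (MPLS) regression with cross-validated
    factor selection, and the full calibration/validation statistics suite
    (RSQ, SEC, SECV, 1-VR, SEP(C), bias, slope, RPD with interpretation bands,
    paired t-test, correlation and strict-parallel reliability). Ships a
    seeded synthetic NIR spectra generator emulating a five-trait legume
    flour study so the complete pipeline can be exercised end to end without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
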