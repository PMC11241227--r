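Package: coagmir
Title: Chemometric Prediction of Milk Coagulation Traits from Mid-Infrared Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building and validating mid-infrared (MIR) prediction
    models of milk coagulation traits (rennet coagulation time, curd-firming
    time, and curd firmness) in the WinISI tradition: water-region masking,
    scatter corrections (SNV, detrend, SNV+D, MSC), gap-segment derivative
    math treatments, modified partial least-squares (mPLS) regression with
    iterative k-fold cross-validation, Global-H and T-statistic outlier
    elimination, calibration/validation splitting, and the standard NIRS
    fitting-statistics panel (SEC, R2 of cross-validation, SEP, R2 of
    external validation, RPD, bias, slope). Includes a seeded generator of
    synthetic milk-like MIR spectra with Beer-Lambert constituent bands,
    scatter artifacts, and censored coagulation references, so the full
    pipeline can be exercised end to end without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
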