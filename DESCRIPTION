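Package: eiscole
Title: Cole-Model Curve Fitting and Classification for Multi-Site
    Electrical Impedance Spectroscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing multi-site electrical impedance
    spectroscopy (EIS) readings of epithelial tissue.  Fits the
    single-dispersion Cole model to complex impedance spectra by bounded
    nonlinear least squares, extracts per-patient features (Cole
    parameters of the mean spectrum and max-min differences across
    reading sites), ranks feature subsets by two-group MANOVA, fits
    polynomial-basis logistic regression classifiers with optional
    clinical dummy covariates, and evaluates them by repeated stratified
    k-fold cross-validation, ROC/AUC and the Youden-index operating
    point.  Includes a synthetic multi-site cohort generator with known
    group structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
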