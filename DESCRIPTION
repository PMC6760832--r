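Package: chemocal
Type: Package
Title: Multivariate Calibration of Overlapping UV Spectra by PLS, OPLS and Support Vector Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for quantifying a drug in the presence of spectrally
    overlapping impurities from UV absorbance spectra. Implements NIPALS
    PLS1 calibration with bootstrap selection of the number of latent
    variables, orthogonal projection to latent structures (OPLS) removal of
    response-orthogonal spectral variation, first-derivative preprocessing,
    linear epsilon-insensitive support vector regression trained by an SMO
    dual solver with k-fold cross-validated grid search over (epsilon, C),
    a Beer-Lambert synthetic mixture-spectra generator reproducing a
    4-level 3-factor calibration design, and the recovery and error
    statistics (RMSEC/RMSEP/RMSECV, percent recovery, t, F, one-way ANOVA)
    used to compare calibration models.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    signal,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071
Config/testthat/edition: 3
RoxygenNote: 7.3.3
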