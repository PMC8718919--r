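Package: qeegnorm
Title: Sex- and Age-Differentiated QEEG Normative Database Modeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for building and validating sex- and age-differentiated
    normative databases of quantitative EEG (QEEG) band power. Provides
    rule-based normative cohort screening (cognitive, emotional, behavioral
    and pre-screening criteria), Welch band-power feature extraction from
    multichannel resting-state EEG, log-transformed penalized-spline
    normative curve fitting per sex with generalized cross-validation,
    Z-score standardization against the fitted norms, a sliding-window
    age-band baseline for comparison, and validation procedures (Z-score
    calibration, cross-model correlation, sex-difference testing, and
    sex-stratified versus pooled anomaly contrasts). A synthetic cohort
    generator emulates the documented age and sex trends in spectral power
    so the whole pipeline can be exercised without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    splines,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
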