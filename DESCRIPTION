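Package: augcls
Title: Augmented Classical Least Squares Calibration for UV
    Spectrophotometric Mixture Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Multivariate calibration of multi-component UV spectra by
    classical least squares (CLS) and three augmented CLS models that
    filter concentration-orthogonal variation before regression:
    orthogonal signal correction (OSC), direct orthogonal signal
    correction (DOSC), and net analyte preprocessing (NAP).  Includes a
    cyclic five-level, five-factor calibration design generator, a
    Beer-Lambert spectra simulator with configurable instrumental
    artifacts, leave-one-out cross-validation with PRESS-based factor
    selection, recovery/RMSEC/RMSEP evaluation with pooled t and
    variance-ratio comparison against reference-method summaries, and
    net-analyte-signal figures of merit (sensitivity, analytical
    sensitivity, selectivity).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
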