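Package: noctglu
Title: Nocturnal Hypoglycemia, Sleep Quality and CGM Sensor Accuracy Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the relationship between nocturnal
    hypoglycemia measured by continuous glucose monitoring (CGM) and
    next-morning subjective sleep quality in type 1 diabetes. Detects
    nocturnal hypoglycemia episodes at the 3.9 and 3.0 mmol/L thresholds,
    derives per-night glycemic metrics (episode count, duration, area under
    the threshold curve, mean glucose, time in range, coefficient of
    variation), fits random-intercept proportional-odds ordinal regression
    of sleep score on those metrics by adaptive Gauss-Hermite quadrature,
    smooths score-versus-glucose relationships with a locally weighted
    running-line smoother with inflection detection, and assesses sensor
    accuracy against capillary references via MARD and Clarke and Parkes
    error grids. Includes a synthetic cohort generator with known ground
    truth so the whole pipeline is testable without patient data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    jsonlite,
    pracma,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
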