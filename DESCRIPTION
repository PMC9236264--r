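Package: ganest
Title: Genetic-Algorithm Feature Selection with Nested Cross-Validation
    for Fatigue-Outcome Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Wrapper feature selection by a genetic algorithm with a
    least-squares linear discriminant (LSLD) fitness, embedded in repeated
    nested stratified cross-validation, for small-sample high-dimensional
    classification of fatigue improvement in rheumatoid arthritis from
    structural MRI morphometrics, diffusion tract metrics or clinical
    variables. Includes soft-margin and RBF support vector machine
    classifiers with inner-loop grid tuning, balanced-accuracy and ROC
    reporting with vertical curve averaging, selection-frequency stability
    analysis, a chromosome-length sweep, and a synthetic-cohort generator
    with planted group effects so that every stage is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    e1071,
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    MASS,
    pROC,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
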