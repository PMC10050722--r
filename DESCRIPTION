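Package: handkin
Title: Handwriting Kinematics for Cognitive-Impairment Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for digital-pen handwriting analysis in
    case-control cognitive-screening studies. Ingests raw pen streams
    (position, timestamp, tip pressure, pen-contact state), segments them
    into strokes, computes a 35-characteristic kinematic feature set
    (pressure, timing, stroke geometry, velocity, acceleration, and
    Shannon-entropy stability measures), screens features with
    normality-gated two-sample tests and Spearman correlations against
    cognitive scores, and evaluates diagnostic performance with a
    seven-classifier harness, self-contained ROC/AUC construction, and
    Youden-optimal operating points. A synthetic-cohort generator emulates
    the group-level kinematic differences reported for Alzheimer's patients
    versus healthy controls so the whole pipeline can be exercised and
    validated without clinical data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    graphics,
    utils,
    tools,
    tibble,
    dplyr,
    readr,
    jsonlite,
    yaml,
    car,
    e1071,
    class,
    rpart,
    randomForest,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    knitr
Config/testthat/edition: 3
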