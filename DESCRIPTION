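Package: rehabpattern
Title: Early Prediction of Physical-Activity Recovery Patterns from
    Wearable Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting the recovery pattern of daily physical
    activity (upward-linear versus S-shape) in older hip-fracture patients
    from the first 5-8 days of continuously monitored activity intensity.
    Implements the accelerometer preprocessing chain (moving-average and
    high-pass Butterworth filtering, daytime signal magnitude area),
    trajectory feature extraction (statistical, amplitude, morphological and
    clinical features over early time windows), correlation-based feature
    selection via symmetrical uncertainty, a classifier suite with stratified
    cross-validation including a cosine k-nearest-neighbour model, per-class
    precision/recall/F1 and micro-F1 evaluation, reconstruction of confusion
    matrices from published rounded precision/recall values, and a synthetic
    rehabilitation-cohort generator for end-to-end validation without patient
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    MASS,
    e1071,
    rpart,
    randomForest,
    xgboost,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
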