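Package: cgmcal
Title: Personalized Calibration of Continuous Glucose Monitoring Readings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Cluster-stratified, personalized calibration of minimally
    invasive continuous glucose monitoring (CGM) sensors. Partitions
    glucose readings into six clinically defined ranges (hypoglycemia
    through critical diabetes), trains a per-cluster error-prediction
    regressor on wearable-derived covariates (activity, posture, heart
    and breath rate, skin temperature, food intake), corrects measured
    values by subtracting the predicted sensor error, and quantifies the
    improvement with MARD, RMSE and Clarke Error Grid Analysis. Includes
    a multilayer-perceptron regressor with exhaustive hyperparameter
    grid search, a six-family model screen, and a synthetic cohort
    generator with a known sensor-error mechanism for end-to-end
    validation without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    e1071,
    randomForest,
    rpart,
    caret,
    ggplot2,
    optparse
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr
Config/testthat/edition: 3
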