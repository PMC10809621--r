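Package: wearcog
Title: Predicting Cognitive Composite Scores from Wrist-Wearable Physiological Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline mapping raw wrist-wearable physiological signals
    (blood volume pulse, electrodermal activity, skin temperature, heart rate and
    inter-beat intervals in the Empatica-E4 CSV dialect) to predictions of
    neuropsychological composite z-scores in mild cognitive impairment. Covers
    signal quality control and 5-minute segmentation, a ~130-feature catalogue of
    heart-rate-variability, electrodermal and temperature measures, Gompertz
    interpolation of sparse longitudinal outcomes, individual centering,
    FDR-screened association analysis, and cross-validated machine-learning
    prediction with leave-one-subject-out and leave-one-interval-out schemes.
    Includes a synthetic-cohort generator with known signal-cognition coupling so
    every stage is verifiable against a recoverable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    pracma,
    lme4,
    glmnet,
    randomForest,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
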