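Package: velogaze
Title: Cyclist Attention from Eye-Tracking: Composite Scoring and
    Hierarchical Ordered Logistic Modelling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to study cyclist attention on campus roads from wearable
    eye-tracking data. Computes per-trial gaze indicators (fixation, saccade
    and blink statistics, lane fixation share, pupil diameter coefficient of
    variation), reduces them to a composite attention score by principal
    component analysis with three ordered attention levels, and models the
    levels with two competing ordinal regressions: a standard cumulative-logit
    model fitted by maximum likelihood and a hierarchical ordered logistic
    model with cyclist-specific thresholds shifted by gaze covariates and a
    random effect, estimated by Metropolis-within-Gibbs sampling. Includes a
    synthetic-data generator that emulates the study design for testing and
    calibration, model evaluation via cross-tables and accuracy, and
    odds-ratio analysis with reference recoding.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
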