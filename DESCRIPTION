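Package: sjrfest
Title: Shoulder-Joint Reaction Force Estimation from Wearable IMU and EMG Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Continuous estimation of the three-dimensional shoulder-joint
    reaction force (SJRF) during wheelchair-related activities of daily
    living from wearable inertial measurement units (IMU) and surface
    electromyography (EMG). Provides a synthetic wheelchair-activity cohort
    generator with known nonlinear force generation, the signal-processing
    chain (zero-phase Butterworth filtering, EMG envelope extraction and
    submaximal normalization, cross-correlation stream synchronization,
    resampling to a shared 25 Hz grid), leave-one-trial-out and
    leave-one-subject-out cross-validation designs, bidirectional LSTM and
    linear feed-forward sequence regressors trained with early stopping,
    evaluation metrics (Pearson correlation, range-normalized RMSE), and
    shoulder-load profiles compared by histogram intersection.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
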