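Package: pulsegrade
Title: Pulse-Wave Biosignal Processing and Transport-Stress Grading for
    Livestock
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for processing wearable photoplethysmography (pulse-wave)
    and infrared body-temperature signals from livestock during transport,
    and for grading transport stress from the extracted physiology.  The
    package implements a recursive band-pass/derivative/moving-window beat
    detector with adaptive two-threshold peak classification, biorthogonal
    wavelet soft-threshold denoising, time-domain heart-rate-variability
    feature extraction (HR, MR, SDNN, RMSSD, pNN50, CV) plus a body
    temperature feature, and a bench of eight multiclass classifiers
    (including a transparent reference gradient-boosted tree ensemble and a
    tuned extreme-gradient-boosting model) that grade stress into comfort,
    stress and intermediate levels.  A synthetic signal and cohort generator
    with known ground truth makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    class,
    e1071,
    jsonlite,
    randomForest,
    signal,
    stats,
    utils,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
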