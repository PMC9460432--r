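Package: fatigueEEG
Title: EEG-Based Fatigue-Level Classification for Watchkeeping Operators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A video-free pipeline for classifying operator fatigue into
    three levels (alert, middle, fatigue) from four-channel EEG. Eyelid
    closure degree is estimated from occipital alpha-band power via a
    published linear model; frontal-channel epochs are decomposed with a
    five-level db5 discrete wavelet transform into 19 time-domain features
    (mean absolute value, standard deviation, root mean square, and
    Shannon wavelet-energy entropy); fused closure-plus-EEG feature rows
    are classified with recurrent networks (GRU, Bi-GRU, LSTM, Bi-LSTM)
    or standard baselines (SVM, k-NN, random forest) under subject-wise
    cross-validation; and per-sample labels are corrected by a
    three-channel majority vote. Ground-truth states come from k-means
    clustering of rudder-order reaction times. A seeded synthetic cohort
    generator emulates the assumed statistical structure of the
    recordings so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    e1071,
    class,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
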