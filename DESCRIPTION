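Package: feree
Title: Facial Expression and Intensity Recognition from Multichannel Facial Surface EMG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for wearable facial expression recognition from 10-channel
    facial surface electromyography (sEMG). Implements sliding-window
    time-domain feature extraction (root mean square and integrated EMG),
    robust-scaler batch normalization based on per-feature medians and
    interquartile ranges, and the FER-EE convolutional network that maps the
    20-dimensional feature vector to probabilities over 7 expression types or
    5 intensity levels. Includes a synthetic sEMG generator with
    action-unit-based channel activation profiles, evaluation procedures
    (confusion matrices, fuzzy intensity scoring, channel ablation,
    cross-batch robustness, classical baselines, streaming label smoothing),
    and a landmark-distance mean-relative-error metric for quantifying how
    much a wearable restricts facial motion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    jsonlite,
    yaml,
    MASS,
    e1071,
    randomForest,
    class
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
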