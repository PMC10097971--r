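Package: drowsEEG
Title: Spectral-Signature Drowsiness Detection from Multichannel EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A passive brain-computer interface pipeline for detecting driver
    drowsiness from multichannel EEG. Implements artifact filtering (notch,
    band-reject and Butterworth low-pass retaining 0.5-40 Hz), Welch power
    spectral density and short-time spectrograms, windowed spectral band-power
    and band-power-ratio features, a three-method feature-ranking ensemble
    (minimum redundancy maximum relevance, chi-square, ReliefF) fused by
    Z-score global predictor importance, multi-classifier evaluation under
    stratified 10-fold cross-validation, confusion-matrix metrics with
    ROC/AUC, and statistical channel-of-interest selection. Includes a
    seedable generator of labelled alert/drowsy synthetic EEG sessions for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    MASS,
    purrr,
    readr,
    rlang,
    rpart,
    e1071,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
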