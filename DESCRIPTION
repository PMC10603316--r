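Package: eegarousal
Title: Static and Dynamic Decoding of Anticipatory EEG Arousal
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Classification of high- versus low-arousal anticipatory
    (pre-stimulus) EEG activity. Provides a deterministic synthetic EEG
    generator (1/f background plus oscillations, with injectable spectral
    and slow-ramp temporal class effects), signal conditioning primitives
    (zero-phase Butterworth and windowed-sinc FIR filtering, common average
    reference, baseline correction, decimation, Welch periodogram),
    band-ratio spectral and decimated temporal feature extraction in both
    static (whole-epoch) and dynamic (sliding 500 ms window) variants,
    squared point-biserial feature reduction with cumulative-score
    thresholding and per-channel scalp aggregation, repeated stratified
    cross-validation of LDA, RBF-SVM, 1-NN and a random benchmark with
    in-fold feature selection, and segment-wise right-tailed t-tests
    against the benchmark with Bonferroni-Holm correction and
    best-accuracy-point detection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    data.table,
    e1071,
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
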