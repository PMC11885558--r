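Package: stecg
Title: R-Peak-Free ECG Arrhythmia Classification with the Stockwell Transform
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for beat-class (AAMI N/S/V/F/Q) arrhythmia classification
    from single-lead ECG without R-peak detection. Provides a preprocessing
    pipeline (long/short windowing, zero-phase low-pass filtering, polyphase
    resampling, smoothness-priors detrending, interquartile-range outlier
    rejection, min-max normalisation), a band-limited discrete Stockwell
    transform with real/imaginary channel decomposition, a hybrid
    ResNeXt-SE convolutional + Transformer-encoder classifier implemented
    natively on BLAS matrix operations, an imbalance-aware training harness
    (SMOTE oversampling, focal loss, rectified Adam, cosine warm-restart and
    exponential schedules, early stopping), a full evaluation metric suite
    (accuracy, per-class F1/sensitivity/precision, Cohen's kappa, multiclass
    Matthews correlation), WFDB record and annotation input/output, and an
    annotated synthetic ECG generator for desk-scale end-to-end studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    signal,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
LinkingTo: Rcpp
Config/testthat/edition: 3
RoxygenNote: 7.3.3
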