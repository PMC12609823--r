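Package: noisefuse
Title: Single- and Multimodal Deep Learning of EEG and EDA Responses to
    Construction Noise Annoyance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies noise-induced annoyance from multichannel EEG and
    wrist electrodermal activity (EDA). Implements the complete analysis
    chain: a synthetic multimodal cohort generator with planted spectral
    (frontal theta / alpha) and sudomotor (SCL, SCR-rate) effects,
    zero-phase EEG/EDA signal conditioning, leakage-safe windowing and
    standardization, a compact 4-block convolutional network on raw EEG
    windows and a two-layer bidirectional LSTM on EDA, AdamW training with
    class-weighted cross-entropy and duplication-plus-noise augmentation,
    temperature-scaled calibration, F1-optimal thresholding, decision-level
    fusion (stacked, weighted, gated) with a validation-gated EEG fallback,
    subject-grouped 5-fold cross-validated evaluation, and a one-factor
    ablation harness. Networks are implemented in C++ (no external deep
    learning runtime).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pROC,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
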