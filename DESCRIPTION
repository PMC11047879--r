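Package: eeggan
Title: Adversarial Augmentation and Compressed-Sensing Evaluation of EEG
    Signal Frames
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for augmenting scarce single-channel EEG data with a
    Wasserstein generative adversarial network (gradient penalty, LSTM
    generator, convolutional critic), including frame preprocessing,
    seeded synthetic EEG-like surrogate signals, curve-similarity metrics
    (RMSE, discrete Frechet distance, dynamic time warping), and a
    compressed-sensing benchmark (sparse binary sensing, residual
    convolutional reconstruction, percentage root-mean-square
    distortion) that measures the benefit of augmented training sets.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    MASS,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
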