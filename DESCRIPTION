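Package: ecgdelin
Title: Robust ECG Delineation and Rhythm Interpretation with a
    Convolutional BiLSTM
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Per-sample delineation of single-lead electrocardiograms:
    discrete-wavelet-transform denoising with soft thresholding,
    beat-to-beat segmentation into fixed-length zero-padded beats, and a
    convolutional bidirectional LSTM that labels every sample as P-wave,
    QRS-complex, T-wave, isoelectric line or zero-padding.  Includes grid
    search over batch size, learning rate and epoch count, node-level
    accuracy/sensitivity/precision evaluation, a rule-based rhythm
    interpreter (normal sinus rhythm, atrial fibrillation, atrial
    flutter, other arrhythmia) driven by P-wave presence and RR-interval
    regularity, a minimal WFDB-style record reader/writer and a seeded
    synthetic-ECG generator with exact ground-truth wave labels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
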