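Package: ecgdelin
Title: Single-Lead ECG Delineation and Rule-Based Atrial Fibrillation Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Delineates short single-lead electrocardiograms into P-wave,
    QRS-complex, T-wave and isoelectric segments with a per-sample
    convolutional bidirectional long short-term memory classifier, after
    multilevel discrete-wavelet denoising (soft thresholding, universal
    threshold rule) and fixed-length beat segmentation.  The predicted
    waveform masks feed a medical-knowledge rule stage that screens records
    for atrial fibrillation from RR-interval irregularity and P-wave
    absence.  Includes a labelled synthetic ECG generator (normal sinus
    rhythm and fibrillation-like rhythms), WFDB/CSV record input and output,
    and confusion-matrix / precision-recall evaluation utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
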