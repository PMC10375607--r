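Package: ecgdelin
Title: Twelve-Lead ECG Delineation with Wavelet Denoising and
    Convolutional-Recurrent Sequence Labeling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for delineating the P wave, QRS complex and T wave of
    12-lead electrocardiograms. Reads WFDB-format records and per-lead
    boundary annotations (the Lobachevsky University Database dialect),
    denoises signals by discrete-wavelet-transform soft thresholding with
    signal-to-noise-ratio ranking of candidate wavelets, segments each lead
    into fixed-length 512-sample beat windows (P onset to next P onset,
    zero padded), and labels every sample as P, QRS, T or isoelectric with
    a family of convolutional networks topped by LSTM, BiLSTM, GRU or
    BiGRU heads, trained with masked categorical cross-entropy. Includes
    per-lead confusion-matrix metrics (accuracy, sensitivity, specificity,
    precision, F1), conversion of label streams to wave intervals with
    boundary-error matching, a synthetic 12-lead ECG generator with exact
    ground-truth boundaries for testing, and an end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
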