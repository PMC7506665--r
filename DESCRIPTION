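Package: avfbruit
Title: Arteriovenous Fistula Bruit Segmentation, Classification and
    Interpretation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing auscultation recordings of
    arteriovenous fistulas (AVF), the vascular access used in
    hemodialysis. The package extracts single-heartbeat bruit segments
    from long recordings via a band-limited energy envelope, spline
    smoothing and convex-range detection; converts beats to fixed-size
    log-mel spectrograms; classifies them into five clinically
    motivated sound classes (normal, hard, high, intermittent,
    whistle) with VGG-style convolutional and convolutional-recurrent
    networks trained with inverse-frequency class weighting; selects
    and stacks per-class best models; and localises the time-frequency
    evidence for a decision with Grad-CAM heatmaps. A seedable
    synthetic bruit generator provides labelled corpora with
    ground-truth beat annotations so the whole pipeline is testable
    without patient data. The neural-network engine (convolution,
    batch normalisation, max pooling, bidirectional GRU/LSTM, softmax,
    Adam) is implemented in RcppArmadillo.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    Rcpp,
    stats,
    tibble,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
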