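Package: nirsax
Title: Decoding Reading-Comprehension State from fNIRS Trials with
    ICEEMDAN and Symbolic Aggregate Approximation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end pipeline for classifying multi-channel functional
    near-infrared spectroscopy (fNIRS) reading trials as understood or
    not understood. Trials are length-standardized by linear
    interpolation, decomposed into intrinsic mode functions with an
    improved complete ensemble empirical mode decomposition with
    adaptive noise (ICEEMDAN) built on a compiled EMD sifting core,
    symbolized with SAX (z-normalization, piecewise aggregate
    approximation, Gaussian-equiprobable breakpoints), augmented by
    triple window shifting, summarized by statistical moments with
    sequential forward feature selection, and classified with k-nearest
    neighbors over exhaustive small channel combinations. Classifier
    quality is reported through confusion-matrix metrics, ROC AUC, and
    the polygon area metric (PAM). A synthetic hemodynamic trial
    generator makes the whole pipeline testable without access to
    recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
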