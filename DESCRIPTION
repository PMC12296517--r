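Package: plvnet
Title: Event-Related Phase-Locking Networks for Epoched EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for event-related phase-synchronization analysis of epoched
    multichannel EEG in cued reaction-time paradigms. Computes Morlet-wavelet
    instantaneous phase, across-trial phase-locking values (PLV) and
    baseline-normalized relative PLV (rPLV) for all electrode pairs, aggregates
    pairwise connectivity into region-of-interest (ROI) network matrices, and
    summarizes weighted electrode-level graphs by global efficiency and average
    clustering. Group-level network comparison is supported through Euclidean
    network distance time courses, principal component analysis of connectivity
    patterns, and cross-validated linear discriminant classification with a
    label-shuffled surrogate control, together with a nonparametric statistical
    layer (pointwise increase tests, Mann-Whitney U contrasts with
    Benjamini-Hochberg correction, behavioral performance summaries, and
    efficiency-reaction-time regression). A synthetic-cohort generator based on
    hierarchically coupled von Mises phase oscillators with 1/f background
    noise provides ground-truth data for validation and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    igraph,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
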