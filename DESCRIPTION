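Package: flightcall
Title: Robust Detection of Avian Flight Calls in Noisy Bioacoustic Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sound event detection for bioacoustic sensor networks, aimed at
    nocturnal flight calls of migratory birds recorded by autonomous
    recording units. Provides a per-channel energy normalization (PCEN)
    time-frequency frontend, long-term quantile summary statistics of the
    acoustic background, a context-adaptive convolutional neural network
    detector with four output-layer formulations (static baseline, adaptive
    weights, adaptive threshold, mixture of experts), sliding-window
    detection in continuous audio with peak picking, event-based
    precision-recall evaluation with bipartite matching at a 500 ms
    tolerance, geometrical and adaptive data augmentation, and a seeded
    generator of synthetic full-night soundscapes with ground truth, so the
    whole pipeline is testable end to end without field recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    igraph,
    jsonlite,
    Matrix,
    Rcpp,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
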