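Package: tftperm
Title: Trial-Frequency Decomposition and Cluster-Based Permutation Tests
    for Reaction-Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of intra-individual reaction-time variability in
    trial-based tasks.  Decomposes a subject's trial-indexed reaction-time
    series with complex Morlet (Gabor) wavelets into a trial-by-frequency
    power map (the "trial frequency of trials" representation), and compares
    such maps between two groups or paired conditions with a two-step
    nonparametric cluster-based permutation test (bin-level permutation
    thresholding followed by max-cluster-mass Monte Carlo inference).
    Includes a time-estimation-task response classifier (correct, early,
    late, missed), descriptive behavioral summaries, a synthetic-cohort
    simulator with controlled burst-like variability structure, and a
    command-line pipeline for reproducible end-to-end runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
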