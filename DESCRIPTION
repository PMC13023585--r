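Package: plvnet
Title: Phase-Locking-Value Brain Network Analysis with Coupled-Oscillator Surrogates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Resting-state EEG brain-network analysis pipeline: phase locking
    value (PLV) connectivity in theta/alpha/beta bands from band-limited
    region time series, sparsity-thresholded binary graph metrics (clustering,
    path length, global/local efficiency) with degree-preserving random-network
    normalization (gamma, lambda, sigma), Network-Based Statistic permutation
    correction for paired connectome contrasts, and within/between
    resting-state-network strength statistics (repeated-measures ANOVA with
    partial eta squared, Friedman and Dunn tests). A synthetic generator of
    phase-coupled region signals with plantable condition-by-time effects
    emulates a two-condition, two-time crossover design so every stage is
    testable without EEG recordings.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
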