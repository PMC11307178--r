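Package: rallydma
Title: Within-Match Performance Fluctuation Analysis for Rally-Based Net Games
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to quantify and test within-match performance fluctuations
    in rally-based net games such as table tennis. Rally-by-rally win/loss
    sequences are smoothed with a double moving average (DMA) interpreted as
    momentary point-winning strength. The package computes the exact expected
    DMA distribution under an independent-rallies binomial model by exhaustive
    enumeration, tests observed DMA distributions against it with a
    Kolmogorov-Smirnov statistic (asymptotic or Monte-Carlo p-values), builds
    a simulated null distribution of DMA kurtosis for per-match z-tests, and
    scores match dominance with an improved competition-performance (CP)
    statistic that penalizes deuce sets. Seeded generators for independent,
    autocorrelated (Markov) and regime-switching rally sequences support
    calibration and power analysis, and a batch driver plus command-line
    interface orchestrate per-match analyses over CSV inputs.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    e1071,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
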