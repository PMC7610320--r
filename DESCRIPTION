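Package: synergait
Title: Muscle Synergy Extraction and Motor Primitive Analysis for Locomotor EMG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the modular analysis of surface electromyography (EMG)
    recorded during walking and running. Implements the standard envelope
    preprocessing chain (zero-phase Butterworth filtering, rectification,
    amplitude normalization and gait-cycle time normalization to 200 points),
    muscle synergy extraction by non-negative matrix factorization with
    multiplicative updates, a plateau-based convergence rule and a linear-fit
    rank-selection heuristic, complexity and duration metrics for motor
    primitives (Higuchi's fractal dimension and full width at half maximum),
    NMF-based clustering of primitives into principal shapes with functional
    classification of synergies, and a ground-truthed synthetic generator of
    modular gait EMG for validation. Includes per-trial and cohort pipelines
    and plain-text interchange formats.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
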