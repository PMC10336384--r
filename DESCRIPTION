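Package: statecausal
Title: State-Space Causality Detection with Continuity Scaling and
    Convergent Cross Sorting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects directed causal links between pairs of time series from
    the geometry of their delay-coordinate reconstructions, implementing two
    attractor-based detectors: continuity scaling (CS), which scores causality
    by the slope of the pre-image neighbourhood radius against the logarithm
    of the image neighbourhood radius, and convergent cross sorting (CCS), a
    rank-based extension of convergent cross mapping. Includes simulators for
    the benchmark systems the detectors are commonly evaluated on (coupled
    logistic maps and their chain/ring networks, the Roessler-Lorenz system,
    and two coupled Roessler oscillators with a tunable frequency ratio),
    measurement-noise injection at a stated signal-to-noise ratio,
    k-nearest-neighbour mutual-information and differential-entropy
    diagnostics, stationary-bootstrap significance testing, and an ROC/AUC
    evaluation harness with length, coupling, noise, frequency and
    bidirectional-grid experiment designs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
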