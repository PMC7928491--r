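Package: sckinetics
Title: Single-Channel Patch-Clamp Kinetics: Simulation, Idealization,
    Dwell-Time and Burst Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the kinetic analysis of single-channel patch-clamp
    recordings of ligand-gated ion channels such as alpha4beta2 nicotinic
    acetylcholine receptors. Provides aggregated continuous-time Markov
    gating models with theoretical dwell-time structure, Gillespie
    simulation of state trajectories rendered as realistic filtered
    current traces, segmental k-means (SKM) and half-amplitude threshold
    idealization, maximum-likelihood fitting of left-truncated exponential
    dwell-time mixtures with log-likelihood-based model selection, burst
    segmentation with critical-time (T_crit) determination and amplitude
    class separation, stability and patch-level quality control, and
    fold-change hypothesis testing of mutant versus wildtype channel
    properties.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    car,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
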