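Package: aqifnet
Title: Deterministic Adaptive Spiking Networks and Their Fit to Population Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates deterministic networks of conductance-based quadratic
    integrate-and-fire neurons with global supralinear inhibitory feedback and
    spike-frequency adaptation, reproducing the spectrum of cortical activity
    regimes from desynchronized tonic firing to up/down-state alternations.
    Provides the summary statistics used to characterize multi-neuron
    recordings (multi-unit activity, its autocorrelation and distribution,
    pairwise and noise correlations), a normalized-cost fitting engine with
    grid search, cost smoothing and a Gibbs/MCMC sampler, stimulus-driven
    simulations with Poisson-likelihood decoding and tuning-width analysis,
    cortical-state analyses (spike-waveform classification, LFP synchrony,
    running-bout segmentation), and synthetic-data generators that stand in
    for in vivo recordings in closed-loop tests.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    minpack.lm,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
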