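Package: coopsync
Title: Simulation and Analysis of Dyadic Cooperation and Inter-Brain Synchrony
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying cooperative behaviour and interpersonal brain
    synchronization (IBS) in two-person (dyadic) fNIRS hyperscanning
    experiments built on the cooperative keystroke paradigm.  Provides a
    generative simulator of the keystroke task under distinct cooperation
    strategies together with its behavioural statistics (trial threshold,
    win/loss scoring, winning ratio, response-time difference and the
    cooperation coefficient), a forward model for two-participant
    multichannel fNIRS recordings with physiological noise, motion artifacts
    and strategy-dependent inter-brain coupling, a preprocessing chain
    (signal-to-noise channel rejection, motion-artifact detection and
    spline correction, modified Beer-Lambert conversion), Morlet wavelet
    transform coherence with band-averaged task-minus-rest IBS, bivariate
    Granger causality, and the group-level statistics (one-sample and
    paired t tests, one-way ANOVA with partial eta squared and Tukey HSD,
    Pearson correlation, Benjamini-Hochberg FDR) needed to carry an entire
    synthetic cohort from task simulation to channel-wise inference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
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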