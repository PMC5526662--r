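Package: stopgamma
Title: Stop-Signal Tapping Electrophysiology: Power, Phase Connectivity
    and Cluster Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for stop-signal finger-tapping
    electrophysiology recordings (scalp EEG plus subthalamic local field
    potentials from deep-brain-stimulation electrodes). Covers signal
    conditioning (DC removal, re-referencing, bipolar derivation, EOG
    regression, anti-aliased resampling), behavioral scoring of stopping
    performance (movement extent, outcome classification, arrhythmia
    exclusion), Hilbert-filterbank time-frequency power with
    regular-tap baseline normalization, gamma-reactivity based bipolar
    contact selection, windowed intersite phase clustering (ISPC)
    connectivity, and group-level inference via cluster-based
    permutation tests, Spearman correlations with bootstrap confidence
    intervals, Fisher-z group tests and FDR correction. A synthetic-data
    generator produces event streams and multichannel signals with known
    ground truth (anticipatory tapping, outcome-coupled gamma bursts,
    movement-locked beta desynchronization, 1/f background, blink
    artifacts) so that every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    nortest,
    Rcpp,
    signal,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
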