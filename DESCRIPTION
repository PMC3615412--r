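Package: entrainkit
Title: Input-Output Entrainment Analysis for Paired Rhythmic Event Trains
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for quantifying entrainment between a rhythmic input (e.g.
    vagal stimulus trains) and a rhythmic motor output (e.g. phrenic nerve
    bursts). Computes instantaneous phase from event onsets, relative-phase
    histograms with the Rayleigh test, sliding-window phase coherence with
    bout/latency/phase-slip detection, the n:m synchronization index
    (phase-locking value), normalized cross-correlograms, and the mutual
    information of instantaneous phases with an interval-shuffling bootstrap
    significance test. Also provides respiratory pattern statistics (period,
    coefficient of variation, apnea index, inspiratory-time reduction, drift
    quality control), a threshold-crossing burst detector for continuous
    traces, and a forced stochastic phase-oscillator simulator with
    wild-type-like, intermediate, and severe phenotype presets for validating
    the full analysis chain.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
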