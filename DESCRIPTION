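Package: seqtime
Title: Sequence-Cell and Population-Trajectory Analysis for Cued-Delay
    Working-Memory Calcium Imaging
Version: 0.1.0
Authors@R:
    person("Seqtime", "Developers", email = "seqtime@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for deconvolved two-photon calcium-imaging
    recordings from a differential delayed-non-match-to-sample (dDNMS)
    olfactory task, in which the identity of the first odor cues the delay
    duration (2.5 or 5.0 s). Provides behavioral scoring (accuracy, lick
    latency, locomotion bouts), conditioning of deconvolved signals (rolling
    mean, z-score floor), trial alignment and binning, odor-specific
    sequence-cell detection by a circular-shuffle permutation test with
    trial-reliability filtering, population-trajectory geometry (distance
    from baseline and speed with sqrt(n) normalization), per-neuron odor
    mutual information, multiclass decoding of elapsed time, and a synthetic
    session generator with planted ground truth so that every stage is
    testable without animal recordings.
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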