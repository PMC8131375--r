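Package: meanet
Title: Network Activity Analysis for Microelectrode Array Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for extracellular network electrophysiology
    from high-density and multiwell microelectrode arrays: zero-phase
    Butterworth bandpass filtering, robust (median absolute deviation)
    noise estimation with negative-peak threshold spike detection and
    sensor quality control, subarray-local zero-lag spike-train synchrony,
    adaptive cumulative-moving-average burst detection with chip-level
    burst features, longitudinal per-chip interpolation with genotype-group
    averaging, multiwell weighted mean firing rates, and rheobase
    estimation from cohort-averaged current-clamp input-output curves.
    Includes a deterministic synthetic-data generator that emulates the
    activity regimes of isogenic control and 16p11.2 deletion/duplication
    dopaminergic neuron cultures with known ground truth, so every analysis
    stage can be validated against simulated recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
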