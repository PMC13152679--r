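Package: duofluor
Title: Dual-Channel Fluorescence Movie Analysis for Contrasting-Affinity
    Dopamine Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for dual-channel fluorescence imaging of
    neurotransmitter sensors with contrasting affinities (a GRAB-like
    genetically encoded indicator imaged alongside a near-infrared
    nanotube catecholamine sensor). Provides delta-F/F extraction under
    pre-stimulus and trial-median baseline conventions, double-exponential
    photobleach correction, zero-phase Butterworth low-pass filtering,
    grid-mask hotspot (ROI) detection with a k-standard-deviation activity
    criterion, rise-decay kinetic fitting (tau-on/tau-off), spontaneous-wave
    detection with event-triggered averaging and response quantification,
    exact small-sample Mann-Whitney and paired-t statistics, and a
    ground-truth synthetic dual-sensor movie generator (Hill-type binding,
    Gaussian release hotspots, photobleaching, shot-like noise) so the whole
    pipeline is verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    minpack.lm,
    signal,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
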