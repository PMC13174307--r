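Package: neurotelem
Title: Telemetry Analysis of Epileptiform Activity, Sleep, Circadian
    Rhythms, and Open-Field Behavior in Mouse EEG/EMG Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for continuous wireless EEG/EMG telemetry
    and open-field behavior in mouse models of brain network dysfunction.
    Provides a synthetic-data generator with known ground truth
    (vigilance states, epileptiform spikes, circadian locomotion and
    temperature, open-field trajectories with behavioral motif labels),
    EDF input/output with artifact masking and Zeitgeber-time alignment,
    band-power and multitaper spectral analysis with aperiodic/periodic
    (1/f) spectral parameterization, baseline-SD epileptiform spike
    detection, rule-based Wake/NREM/REM sleep staging with hypnogram
    metrics, circadian 15-minute profiling with equal-frequency activity
    binning, and open-field zone/heatmap spatial analysis of pose
    trajectories and behavioral motifs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    MASS,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
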