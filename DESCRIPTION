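Package: semgfatigue
Title: Quantification of Muscle Fatigue from Surface EMG High-Frequency Components
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the degree of muscle fatigue during cyclical movements
    from single-channel surface electromyography (sEMG). The pipeline
    conditions the raw signal (10-400 Hz band-pass, 50 Hz notch), extracts the
    highest-frequency intrinsic mode function by ensemble empirical mode
    decomposition (EEMD), tracks the median frequency (MF) of that component in
    sliding windows, fits the MF drift with a linear model, calibrates a
    per-subject standardized median-frequency distribution range (SMFDR) from
    training sessions, and maps fitted MF onto an N-level fatigue scale LF in
    [0, 1]. A seeded synthetic sEMG generator with a programmable MF trajectory
    makes every stage testable without subject recordings. Includes a
    command-line driver for the simulate/calibrate/estimate workflow.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    jsonlite,
    data.table,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
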