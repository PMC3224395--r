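Package: semgpipe
Title: Surface EMG Hand-Gesture Classification Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and classification pipeline for multi-channel
    surface electromyography (sEMG) hand-gesture recognition. Generates
    seeded, annotated 4-channel forearm sEMG recordings with per-gesture
    amplitude structure, segments them into overlapping windows, extracts
    waveform-length, root-mean-square and fourth-order autoregressive
    features per channel, tunes a one-vs-one multi-class radial basis
    function support vector machine by cross-validated grid search, and
    evaluates per-subject and cohort-level classification performance
    including confusion-structure and strength/accuracy summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    e1071,
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
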