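Package: ecgtriage
Title: Attention-Augmented 1D CNN Heartbeat Classification and Rule-Based Vitals Triage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for offline analysis of remote-health-monitoring telemetry:
    a synthetic generator for five-class ECG beat morphologies and vitals
    streams, the standard ECG preprocessing chain (zero-phase Butterworth
    bandpass, resampling, per-beat z-normalization, R-peak beat segmentation),
    a from-scratch attention-augmented one-dimensional convolutional neural
    network for five-class heartbeat classification (normal, supraventricular
    premature, premature ventricular contraction, fusion, unclassifiable),
    first-principles evaluation metrics with grid search, and a rule-based
    triage engine for body temperature, age-banded heart rate and SpO2 with a
    report-and-alarm decision.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    pracma,
    rlang,
    signal,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
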