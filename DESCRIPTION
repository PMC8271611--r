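Package: hrvagree
Title: Device Agreement Analysis for Heart Rate Variability from Paired ECG
    Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates paired two-device single-lead ECG recordings of a
    blocked psychophysiological session with known ground truth, runs a
    reproducible signal-processing chain (zero-phase Butterworth filtering,
    artifact flagging and interpolation, R-peak detection with physiologic
    rate constraints, beat correction, cross-device alignment), extracts
    per-block heart-rate-variability features (HR, RMSSD, LF, HF, LF/HF),
    and quantifies between-device agreement with ICC(2,1) including the
    F-based lower 95 percent confidence bound and repeated-measures
    Bland-Altman limits of agreement with outside-LoA fractions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
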