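Package: ecgtriage
Title: ECG Denoising, QRS Detection, and Atrial Fibrillation / Ischemia Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A software re-creation of the signal-processing stack of a
    portable single-lead ECG monitor: Butterworth highpass/notch/lowpass
    digital filtering, Daubechies-8 wavelet decomposition for baseline-wander
    removal and scale-selective QRS complex detection, Poincare-plot
    interbeat-interval features for atrial fibrillation screening, ST-segment
    morphology features for myocardial ischemia, and support-vector-machine
    classification of 10-second sliding windows into normal rhythm, atrial
    fibrillation, or ischemia.  Includes a synthetic ECG generator with the
    three noise-stress noise types (baseline wander, muscle artifact,
    electrode motion) mixed at exact target signal-to-noise ratios, so the
    whole pipeline is testable offline, plus evaluation utilities
    (SNR-improvement tables, periodogram-PSD similarity, cross-validated
    sensitivity and specificity).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    e1071,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
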