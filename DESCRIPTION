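Package: eegic
Title: Quality-Controlled Segmentation and Independent-Component Feature
    Extraction for Long-Term Scalp EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns long-term 19-channel 10-20 scalp EEG into
    quality-controlled segments and labelled independent-component (IC)
    samples. Implements band-pass and notch filtering, detection and
    excision (with 10 s margins) of flatlines, amplifier saturation and
    global high-amplitude movement artifacts, 10-minute segmentation with
    per-channel quality control, electrode-pop repair and whole-channel
    repair by spherical-spline interpolation, average re-referencing,
    extended-infomax independent component analysis, and per-component
    features: Welch power spectra over 1-90 Hz and 67 x 67 scalp
    topographic maps. Includes readers, writers and a validator for the
    plain-text dataset layout (training/test splits of artifact,
    not-artifact and ICA-weight files) and a synthetic-EEG generator with
    ground-truth artifact annotations so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
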