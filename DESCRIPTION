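Package: fwavekit
Title: Automated F-Wave Corridor Extraction and Motor Unit Number
    Estimation from EMG Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Fully automated extraction and analysis of F-waves from
    multi-trace surface EMG recordings. Locates the F-wave corridor from
    the sum of all traces and its autocorrelation function with a set of
    validation and fallback rules, removes the stimulus-artifact prefix,
    denoises traces by Daubechies-12 wavelet shrinkage, corrects per-trace
    baselines by linear least squares without waveform distortion, detects
    repeater F-waves with a two-pass similarity procedure, and computes
    F-wave features (repeater counts, persistence, surface motor unit
    potential amplitudes) and motor unit number estimates (F-MUNE). A
    synthetic-recording generator with full ground truth supports testing
    every stage without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
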