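Package: prvkit
Title: Pulse Rate Variability from Contact and Camera-Based Photoplethysmography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for pulse rate variability (PRV) analysis
    from blood volume pulse (BVP) signals, including camera-based remote
    photoplethysmography (rPPG). Extracts a continuous BVP from skin-colored
    video frames by chrominance analysis in YCbCr space; cleans inter-beat
    intervals by cropping, overlapped segmentation, quadratic-spline
    resampling, zero-phase Butterworth bandpass filtering, peak detection and
    z-score based outlier replacement (PPI to NNI normalization); computes
    time- and frequency-domain PRV indices (mean NN, SDNN, LFnu, HFnu, LF/HF)
    from the interval tachogram; and scores agreement between a contact
    reference channel and a camera test channel with mean absolute percentage
    error (MAPE) tables, improvement deltas and correlation coefficients.
    Includes an integral pulse frequency modulation (IPFM) simulator that
    generates paired contact/camera recordings with prescribed low- and
    high-frequency autonomic modulation, motion-artifact episodes, and
    pulse-modulated synthetic skin video frames.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    pracma,
    png,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
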