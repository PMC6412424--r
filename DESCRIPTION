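Package: ecgparafit
Title: ECG Fiducial-Point Delineation by Sliding-Window Parabola Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects the P, Q, R, S and T peaks of single-lead electrocardiogram
    recordings with a low-cost sliding-window least-squares parabola fit. A
    window is swept across the signal and at each centre a vertex-centred
    parabola is fitted; local minima of the quadratic-mean fit error mark wave
    apices, and the opening coefficient separates true waves from line-like
    (isoelectric) stretches. Includes Butterworth low-pass filtering and
    polynomial baseline-wander removal, R-peak detection, isoelectric-level
    estimation, beat segmentation on the mean R-R interval, narrow-window
    P/Q/S/T delineation relative to R, a temporal-tolerance sensitivity metric
    for benchmarking against reference annotations, readers for WFDB and
    delimited-text signals, and a synthetic ECG generator with exact
    ground-truth fiducials for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    jsonlite
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
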