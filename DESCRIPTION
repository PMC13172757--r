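Package: taplab
Title: Kinematic Analysis of Video-Derived Finger-Tapping Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify bradykinesia from markerless hand-landmark
    recordings of the MDS-UPDRS finger-tapping task. The package derives an
    index-thumb aperture waveform from per-frame fingertip coordinates,
    conditions it (linear detrending, Savitzky-Golay smoothing, resampling,
    zero-phase Butterworth low-pass), segments tap cycles with a
    refractory-interval peak detector, and extracts four clinically aligned
    features: tapping velocity, amplitude decrement, amplitude coefficient
    of variation and instantaneous-frequency coefficient of variation.
    Diagnostic and correlation statistics (Mann-Whitney U with the AUC-U
    identity, DeLong ROC confidence intervals, Youden cutoffs, binary
    logistic regression with Cox-Snell and Nagelkerke R2, Spearman
    correlations with bootstrap confidence intervals and Benjamini-Hochberg
    correction) operate on cohort feature tables. A seeded synthetic
    tapping-waveform generator with controllable amplitude and rhythm
    variability supports validation without patient videos.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    signal,
    pROC,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
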