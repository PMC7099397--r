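Package: ecgbeats
Title: ECG Beat Classification with Convolutional and Recurrent Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for five-class (AAMI/IEC EC57) electrocardiographic
    beat classification on single-lead recordings. Provides reading and
    writing of ECG records with beat annotations (WFDB and CSV dialects),
    a seeded synthetic ECG generator with class-specific beat morphologies
    and common noise families, a preprocessing pipeline (resampling,
    loose-contact exclusion, zero-phase bandpass filtering, R-peak
    detection, three-beat segmentation, short-time Fourier transform),
    bucketed variable-length batching with per-epoch class rebalancing,
    baseline (two convolutions + two vanilla recurrent layers) and
    lightweight (one convolution + fused recurrent layer) classifiers with
    an equivalence contract between the stepwise and fused recurrent
    forward passes, and confusion-matrix based evaluation (per-class
    accuracy, sensitivity, specificity, positive predictive value, overall
    accuracy, per-subject reports).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    signal,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
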