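Package: wscec
Title: ECG Beat Classification via Wasserstein Scalar Curvature of Local-Covariance Point Clouds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transforms single-lead ECG heartbeats into point clouds on the
    manifold of symmetric positive-definite matrices and classifies heart-disease
    type from the curvature of those clouds. Each denoised 300-sample beat is
    embedded into R^d by a sliding-window FFT, converted point-wise to local
    k-nearest-neighbour scatter matrices, and summarised by the scalar curvature
    of the Bures-Wasserstein metric at every matrix. The dispersion of the
    curvature histogram (median transverse dispersion, corrected-standard-deviation
    longitudinal dispersion) places each beat in a rectangular symptom-description
    domain of the dispersion plane, yielding a training-free diagnosis among
    normal, atrial-abnormal, ventricular-abnormal and bundle-branch-block classes.
    Includes preprocessing (Butterworth low-pass, R-peak detection, beat
    segmentation), a brute-force curvature oracle for validation, a synthetic
    PQRST beat generator for seven rhythm classes, and classification metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    zoo,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
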