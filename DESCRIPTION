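Package: pathsig
Title: Path-Signature and Lead-Matrix Features for Multichannel Biosignals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature extraction and classification for multichannel biosignal
    (EEG) epochs based on truncated path signatures. Computes exact truncated
    signatures of piecewise-linear multichannel paths with streaming (Chen)
    updates, builds skew-symmetric lead matrices from the level-2 signature and
    recovers the cyclic (lead-lag) order of phase-lagged oscillations from
    their eigenvector phases, turns lead matrices into symmetric positive
    definite feature matrices, and classifies on the SPD manifold under the
    affine-invariant Riemannian metric (minimum distance to mean and
    tangent-space classifiers). Includes synthetic generators for phase-lagged
    sine systems and two-class motor-imagery-like epochs, band-pass
    preprocessing, cross-validation study runners, CSV/EDF epoch I/O and a
    small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    signal,
    e1071,
    glmnet,
    randomForest,
    nnet,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
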