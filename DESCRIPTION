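Package: swimrep
Title: Swim-Rep Fusion Networks with Criss-Cross Polarized Attention for ECG Beat Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale implementation of a hybrid convolution/transformer image
    classification backbone and its attention and fusion blocks: sparse recurrent
    criss-cross attention fused with polarized self-attention (FRCPA), a five-branch
    strip-pooling feature fusion module (MPF), structurally reparameterizable
    convolution blocks, and shifted-window multi-head self-attention, assembled into a
    four-stage network. Includes a complete MIT-BIH-style ECG beat-classification
    pipeline (WFDB reading, wavelet baseline-wander removal, 60 Hz notch filtering,
    AAMI five-class beat labeling, beat windowing), a pseudo-label semi-supervised
    training protocol, evaluation metrics, operator-level parameter and FLOP
    accounting, and deterministic synthetic ECG and texture-image generators so every
    stage is testable without external data. All tensor operations, including
    reverse-mode automatic differentiation, are implemented in base R on top of BLAS
    matrix products.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    signal,
    pROC,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
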