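Package: giwtnet
Title: Ghost-Inception and Wavelet-Transform Convolutional Detection of Insect Pests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds, inspects and trains a lightweight single-stage object
    detector for bark-beetle (Scolytinae) trap images. The backbone couples a
    ghost-inception downsampling convolution (GIConv) with wavelet-transform
    depthwise convolutions (WTConv) inside split-transform-concat stages, and
    squeeze-and-excitation channel attention is applied between the feature
    fusion neck and the detection head. The package provides orthonormal 2-D
    Haar analysis/synthesis, an analytic multiply-accumulate cost model with
    instrumented verification, per-layer parameter and GFLOP accounting
    against a reference layer table, Pascal-VOC annotation I/O, mosaic and
    mixup augmentation, a synthetic annotated-scene generator emulating the
    statistical structure of bark-beetle trap imagery, detection metrics
    (precision, recall, F1, mAP over IoU thresholds), and a CPU training loop
    built on a compact reverse-mode automatic differentiation engine.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    png,
    xml2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
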