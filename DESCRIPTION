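Package: spineseg
Title: Inception-Enhanced Dual-Output U-Net for Lumbar Spine MRI Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semantic segmentation of sagittal lumbar-spine MRI with an enhanced
    U-Net: an Inception multi-scale block replaces the first encoder stage and an
    auxiliary softmax head at the 8x8 bottleneck provides deep supervision. The
    package contains a native CPU implementation of the network (convolution,
    batch normalisation, pooling and transposed-convolution layers with full
    backpropagation and Adam optimisation), exact closed-form parameter
    accounting, the preprocessing pipeline from labelled MRI volumes to
    training-ready slice pairs, Dice/focal/cross-entropy segmentation losses,
    pixel and boundary evaluation metrics (mIoU, Hausdorff distance, ASSD),
    Grad-CAM explanations, and a seeded synthetic spine-phantom generator so the
    whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    RNifti,
    withr,
    stats,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    yaml,
    png
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
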