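Package: sharpseg
Title: Sharp Attention U-Net Segmentation for Breast Ultrasound Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for lesion segmentation in grayscale breast ultrasound
    images. Implements an encoder-decoder (U-Net) segmentation family --
    plain U-Net, Sharp U-Net (fixed Laplacian sharpening of skip features),
    Attention U-Net (additive attention gates on skip connections), and the
    combined Sharp Attention U-Net -- together with contrast-limited adaptive
    histogram equalization (CLAHE) preprocessing, paired image/mask affine
    augmentation, a BCE-Dice composite loss, a pixel-wise evaluation metric
    suite, and pairwise model comparison by pixel-wise McNemar tests with
    Bonferroni correction. A synthetic speckle-phantom generator produces
    BUSI-style datasets (normal/benign/malignant, PNG image/mask pairs) so
    the whole pipeline runs end to end without external data. The network
    engine (convolution, pooling, transposed convolution and their gradients,
    plus Adam) is implemented in compiled code within the package.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    png,
    pROC,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
SystemRequirements: C++17
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
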