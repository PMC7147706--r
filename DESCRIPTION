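Package: dermoseg
Title: Skin Lesion Segmentation from Dermoscopic Images with Hair Removal
    and a Res-Unet
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for segmenting skin lesions in dermoscopic images. Implements
    a morphological hair-removal stage (black top-hat with a 17x17 cross
    structuring element followed by fast-marching inpainting), image
    preprocessing (resizing to network resolution and per-image
    standardization), a Res-Unet segmentation network (ResNet-50 bottleneck
    encoder with a U-Net style decoder) with training via Adam on pixel-wise
    binary cross-entropy, and evaluation through Jaccard, Dice, sensitivity,
    specificity, pixel accuracy and pooled ROC/AUC. A synthetic dermoscopy
    image generator with exact ground-truth lesion and hair masks makes the
    whole pipeline testable without any external dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jpeg,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
SystemRequirements: C++17
Config/testthat/edition: 3
NeedsCompilation: yes
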