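Package: buslesion
Title: Breast-Ultrasound Lesion Detection Toolkit with Segmentation-Based Enhancement
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for breast-ultrasound lesion detection studies: synthetic
    ultrasound-like phantom generation (speckled, hypoechoic lesions with
    ground-truth masks), a three-step contrast-enhancement chain (contrast
    limited adaptive histogram equalization, Perona-Malik anisotropic
    diffusion, and segmentation-based enhancement), conversion of lesion
    shape masks into detection bounding-box labels, a recurrent-residual
    attention U-Net (R2AttU-Net) lesion segmenter trainable at desk scale,
    and object-detection evaluation metrics (IoU, precision, recall,
    precision-recall curves, AP and mAP) with annotation and prediction
    input/output in CSV and COCO-style JSON.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
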