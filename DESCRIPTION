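Package: msdaspnet
Title: Dual-Attention Spatial-Pyramid Network for Multiple Sclerosis
    Lesion Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end toolkit for segmenting hyperintense multiple
    sclerosis lesions on axial FLAIR brain MRI slices with a U-shaped
    convolutional network (MS-DASPNet): a VGG-16-topology encoder, an
    atrous spatial pyramid pooling bottleneck, and dual-headed
    (spatial + channel) attention gates on the skip connections. Includes
    a synthetic FLAIR phantom generator with exact ground-truth lesion
    masks, the full preprocessing chain (axial slicing, lesion-based
    slice selection, Otsu/morphology skull stripping, non-local-means
    denoising, polynomial bias-field correction, resizing), geometric
    co-augmentation, binary cross-entropy training with Adam and
    patient-disjoint splits, a six-metric segmentation evaluation panel
    (Dice, Jaccard, precision, sensitivity, specificity, false positive
    rate), and Grad-CAM attention maps. The network layers and their
    backward passes are implemented in 'RcppArmadillo'.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    EBImage,
    png,
    yaml,
    jsonlite,
    stats,
    utils,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
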