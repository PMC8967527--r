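Package: noduleflow
Title: Multiposition Lung Nodule Segmentation and Spiculation Recognition for CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Three-stage analysis of thoracic CT volumes: attention-gated
    encoder-decoder segmentation of the lung parenchyma with a dense atrous
    convolution bottleneck, 2.5D multiposition (axial/coronal/sagittal)
    nodule segmentation with a five-level same-size U-Net and a bidirectional
    feature pyramid, and spiculation-sign recognition from radiomics and
    morphological features selected by t-tests and the LASSO. Includes a
    synthetic CT phantom generator with exact ground truth, NIfTI volume I/O
    with Hounsfield window/level display transforms, connected-component
    circularity screening of nodule candidates, and the overlap (Md/Vd/Ud/CM)
    and recognition (SEN/SPE/FPF, ROC) evaluation metrics. All neural-network
    layers (dilated and transposed convolutions, attention gates, normalized
    pyramid fusion) are implemented natively with analytic gradients.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    glmnet,
    e1071
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    png,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
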