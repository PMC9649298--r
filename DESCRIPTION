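Package: mcunet
Title: Multimodule Concatenation U-Net for Retinal Vessel Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained implementation of MC-UNet, a lightweight
    U-shaped encoder/decoder network for segmenting blood vessels in
    fundus photographs. The bottleneck concatenates a spatial-attention
    branch with a dense-atrous-convolution and multikernel max-pooling
    branch to capture local and global vascular context. Includes the
    reusable building blocks (double convolution with DropBlock and
    batch normalisation, dilated convolution, multikernel pooling,
    spatial attention), a reverse-mode differentiation tape and Adam
    optimiser so the network can be trained on the CPU, field-of-view
    masked evaluation metrics (accuracy, sensitivity, specificity,
    ROC/AUC, F1), readers for the public fundus dataset layouts, and a
    procedural generator of fundus-like image/vessel-mask/FOV triples
    so the whole system is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    png,
    tiff,
    yaml,
    stats,
    utils,
    tools,
    grDevices
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
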