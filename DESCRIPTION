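Package: cgenet
Title: Lightweight Ghost-Convolution Network with PCA-Based Channel
    Attention for Insect Image Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds, trains and profiles CGENet, a lightweight
    convolutional classifier for locust and grasshopper genus
    recognition. The network combines an EfficientNet-B0 backbone with
    ghost-convolution bottlenecks carrying efficient channel attention
    (ECA), and a parameter-free channel-wise principal-component
    attention (CPCA) stage computed from the eigendecomposition of the
    channel covariance of feature maps. Includes exact parameter and
    multiply-accumulate accounting, an image-folder data pipeline with
    stratified splits and affine augmentation, a synthetic
    class-separable image generator for offline testing, cross-entropy
    training with SGD/Adam and cosine or exponential learning-rate
    schedules, transfer learning, macro one-vs-rest evaluation metrics,
    k-fold paired model comparison, and Grad-CAM heatmaps.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    EBImage,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
SystemRequirements: C++17
NeedsCompilation: yes
Config/testthat/edition: 3
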