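Package: radrot
Title: Rotation Robustness of Wavelet and Non-Wavelet Radiomic Features
Version: 0.1.0
Authors@R:
    person("radrot", "maintainers", email = "radrot@example.org", role = c("aut", "cre"))
Description: Tools to audit the rotation robustness of three-dimensional
    radiomic texture features. Provides a synthetic CT-like phantom
    generator with orientation-bearing texture, image pre-processing
    (Otsu-based z-score normalization, mask island removal, isotropic
    resampling, fixed-bin-width discretization), an 18-channel imaging
    filter bank (one-level undecimated Coiflet-1 wavelet decomposition,
    Laplacian of Gaussian, intensity transforms, gradient magnitude,
    spherical local binary patterns), 93 gray-level texture features per
    channel plus 14 shape features, a rotation-perturbation simulator with
    identity-resampled baselines, feature-level stability statistics
    (percentage difference, IQR with confidence intervals, Spearman rank
    trends with effect-size strata), and a train-on-original /
    test-on-rotated repeated cross-validation protocol comparing
    wavelet-based and non-wavelet feature partitions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    glmnet,
    FNN
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
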