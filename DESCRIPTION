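Package: tvanet
Title: Visual Attention Parameters and Intrinsic Brain Network Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maximum-likelihood estimation of the four independent visual
    attention parameters of Bundesen's theory of visual attention (TVA) --
    visual processing speed C, visual short-term memory capacity K, top-down
    control alpha and spatial laterality w_lat -- from whole- and
    partial-report trial data, together with a resting-state functional
    connectivity group pipeline: nuisance regression, Gaussian smoothing,
    motion and tSNR quality control, group PCA+ICA decomposition, spatial
    template matching, two-stage dual regression, intra- and inter-network
    connectivity statistics with permutation cluster-extent family-wise error
    control and Bonferroni correction across networks. Includes a synthetic
    data module that simulates trial tables from the fixed-capacity
    exponential race model and small 4D resting-state images with planted
    network structure and known ground truth, so the full analysis chain can
    be exercised and calibrated without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    RNifti,
    jsonlite,
    yaml,
    lhs
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
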