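Package: headforge
Title: Synthetic Head Phantoms, Multi-Rater Segmentation Consensus, and
    Quasi-Static Transcranial Stimulation Modelling
Version: 0.1.0
Authors@R:
    person("Headforge", "Developers", email = "headforge@example.org",
           role = c("aut", "cre"))
Description: A desk-scale pipeline for building and validating volumetric
    head models: an analytic multi-tissue head-phantom generator with known
    ground truth, semi-automatic segmentation primitives (smoothing,
    thresholding, region growing, k-means, morphology, inter-slice
    interpolation), normalized-mutual-information affine registration,
    STAPLE expectation-maximization multi-rater consensus with Dice and
    modified-Hausdorff validation statistics, conformal multi-region
    surface extraction with Taubin smoothing and guarded edge-collapse
    simplification, diffusion-tensor fitting with anisotropic conductivity
    mapping, and quasi-electrostatic finite-volume/finite-element solvers
    for transcranial alternating current stimulation montages.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    minqa,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
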