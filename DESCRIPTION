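Package: funcoord
Title: Functional Coordinates for Nonlinear Dependence Between Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Characterizes the statistical dependence between two signals
    (for example BOLD time courses of a seed region and a target voxel) as a
    vector of projections onto normalized probabilists' Hermite polynomials,
    extending Pearson functional connectivity to nonlinear and U-shaped
    interactions. Provides the orthogonal-series coordinate estimator as a
    classed model object with the usual methods, synthetic validation data
    generators, a seed-to-voxel mapping pipeline with CompCor-style nuisance
    removal and NIfTI input/output, k-means clustering of interaction types
    with AIC elbow model selection, and sign-flip permutation inference with
    cluster-level family-wise error correction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    pracma,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
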