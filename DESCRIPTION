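Package: petconn
Title: Individualized Whole-Body PET Connectomics
Version: 0.1.0
Authors@R:
    person("petconn", "developers", email = "petconn@example.org", role = c("aut", "cre"))
Description: Builds subject-level organ-interaction networks ("connectomes")
    from voxel-wise standardized uptake value (SUV) distributions of
    whole-body PET scans. Organ point clouds are reduced by a spatially-aware
    iterative compression, pairwise organ links are scored by the energy
    distance between SUV distributions with a mutual-information correction
    and exponential similarity, and organ-level graphs are reduced to 13
    anatomical regions of interest. Individual deviation from a control
    cohort is quantified by kernel-density residual networks; disease status
    is classified with a small graph convolutional network (with edge
    ablation saliency) and a regularized logistic baseline; and the whole
    pipeline is stress-tested under simulated segmentation-boundary noise.
    Includes a seeded synthetic phantom generator so the full pipeline is
    testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Matrix,
    glmnet,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
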