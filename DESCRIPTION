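Package: fcdmap
Title: Surface-Based Lesion Mapping and Outcome Modelling for Focal Cortical Dysplasia
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for surface-based analysis of focal cortical dysplasia (FCD)
    lesion cohorts on a template cortical mesh. Builds lesion frequency and
    likelihood atlases, quantifies atlas stability against sample size with
    bootstrap learning curves, runs vertexwise permutation-based association
    tests between lesion location and clinical factors, tests map-map
    correlations against spherical-rotation (spin) nulls, fits and
    cross-validates patient-level logistic models of postsurgical seizure
    freedom, and screens all pairwise variable associations with
    false-discovery-rate control. Includes a synthetic-cohort generator
    (icosphere template, geodesic-disc lesions, planted covariate couplings
    and outcome model) so every analysis stage can be exercised end to end
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Matrix,
    igraph,
    car,
    e1071,
    minpack.lm,
    jsonlite,
    RNifti,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
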