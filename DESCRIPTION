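Package: morphkit
Title: Morphometricity, Brain-Wide Association and Brain-Based Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Statistical toolkit for high-dimensional gray-matter analyses
    downstream of T1-weighted MRI processing. Provides quality control and
    descriptive statistics (skewness, kurtosis, bias-adjusted sumR2) for
    voxel- and vertex-wise feature matrices, morphometric relatedness
    matrices and restricted maximum likelihood (REML) estimation of
    morphometricity with single and multiple variance components,
    mass-univariate brain-wide association with empirical family-wise error
    calibration from simulated null traits, k-nearest-neighbour spatial
    cluster detection with region-of-interest annotation and robustness,
    replication analysis, and linear/BLUP brain-based prediction. A synthetic
    data generator with spatially correlated smooth random fields, tunable
    non-normality and traits of known morphometricity makes the whole
    pipeline testable end to end without access-restricted imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
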