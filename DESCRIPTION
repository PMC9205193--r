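Package: netCFM
Title: Two-Level Coupled Feature Representation for Brain Network
    Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds coupled feature representations of regional gray-matter
    volume measures organised into brain networks, and classifies two-group
    neuroimaging cohorts with them.  Within each network, regional features
    are expanded to integer powers and coupled through significance-revised
    Pearson correlation matrices with factorial (Taylor-like) damping
    weights; between networks, coupling is captured by the leading canonical
    correlations of pairwise canonical correlation analysis on the networks'
    regional feature blocks.  The package also derives networks and regional
    features from subjects-by-voxels gray-matter matrices via eigenvalue-based
    minimum description length order selection and fixed-point independent
    component analysis, classifies the assembled designs with a block-wise
    AdaBoost ensemble of sample-weighted linear support vector machines under
    stratified cross-validation, and simulates two-group datasets with known
    network structure for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
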