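Package: cpmr
Title: Connectome-Based Predictive Modeling of Regional Pathology and Cognition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts scalar phenotypes (regional tau or amyloid-beta PET burden,
    cognitive scores) from resting-state functional connectomes using
    connectome-based predictive modeling (CPM): framewise-displacement censoring,
    global-signal regression and run concatenation of parcellated time series;
    Spearman edge selection into positive and negative masks; network-strength
    summation and ordinary least squares; k-fold cross-validation with iteration
    averaging and a permutation null; consensus masks, node degree and
    network-pair aggregation over a 449-node cortical/cerebellar/subcortical
    parcellation. Includes a synthetic cohort generator with planted
    edge-phenotype couplings so every stage is testable without private data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    MASS,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    withr,
    yaml,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
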