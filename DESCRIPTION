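Package: divcast
Title: Near-Real-Time Monitoring of Species Richness and Phylogenetic
    Diversity from Remotely Sensed Climate
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An indirect remote-sensing framework for monitoring
    biodiversity change. Derives the 19 bioclimatic summaries and annual
    NDVI medians from monthly climate grids, prunes multicollinear
    predictors by stepwise variance-inflation-factor elimination, builds
    per-pixel species richness and Faith's phylogenetic diversity
    surfaces from range rasters or occurrence records plus a phylogeny,
    fits spatially block-cross-validated ensembles of four regression
    learners weighted by inverse RMSE, projects them onto yearly
    predictor sets, maps per-pixel diversity trends and richness/PD
    mismatch, and validates predicted direction of change against
    observed inventories with a permutation null. Includes a synthetic
    landscape generator so the whole pipeline runs end-to-end with known
    ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ape,
    ranger,
    nnet,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    picante,
    withr,
    optparse,
    glmnet
Config/testthat/edition: 3
RoxygenNote: 7.3.3
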