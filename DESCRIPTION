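Package: beltmap
Title: Split-Belt Gait Adaptation Metrics and Voxelwise Brain-Behavior Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantifies adaptation to split-belt treadmill walking from
    motion-capture marker trajectories (per-step gait parameters, percent
    change from baseline, between-feet symmetry, plateau detection and
    magnitude-at-plateau) and relates the resulting per-subject symmetry
    scores to voxelwise structural brain maps through mass-univariate
    linear models with nuisance covariates, threshold-free cluster
    enhancement (TFCE), permutation-based family-wise error control and
    atlas-labelled cluster reporting. Includes a synthetic-cohort module
    that generates gait step series, continuous marker trials and
    brain-metric maps with known ground truth so the whole pipeline is
    testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    pracma,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
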