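Package: ssdu
Title: Subspace Semidefinite-Programming-Based Underestimation for Protein Docking Refinement
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic global optimization for the refinement stage of
    rigid-body protein-protein docking. An input ensemble of receptor-ligand
    conformations (6D rigid-body placements with energies) is clustered with
    DBSCAN, each cluster's energy landscape is underestimated by an SOS-convex
    polynomial fitted by semidefinite programming in a 3D PCA-derived
    "permissive" subspace, sampling is biased toward each underestimator's
    minimum, and new conformations are merged and energy-filtered over several
    iterations. Includes a synthetic multi-funnel landscape generator with
    ground truth, a toy Lennard-Jones/Coulomb rigid-body energy, and a
    post-processing stage that clusters the refined ensemble greedily,
    extracts per-cluster features, and ranks clusters with a random forest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    pROC,
    purrr,
    randomForest,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    bio3d,
    igraph,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
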