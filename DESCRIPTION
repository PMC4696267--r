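Package: irvoter
Title: Influence-Relevance Voting for Ligand-Based Target Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Ligand-based virtual screening and target prediction built around
    the influence-relevance voter (IRV), a shallow neural network that scores a
    query molecule from the similarities, ranks and activity classes of its k
    nearest training neighbors, and its potency-sensitive variant (PS-IRV)
    whose neighbor votes are indexed by EC50 potency class rather than a single
    binary label. Includes circular-substructure fingerprints with Tanimoto
    similarity, the untrained similarity baselines (MeanSim, MaxSim, kNN),
    similarity-feature random forests and Tanimoto-kernel support vector
    machines, tenfold cross-validation, simulated screens against random
    negative pools, training-set augmentation with random negatives, AUC and
    enrichment metrics, reliability (calibration) curves, paired per-target
    comparisons, and a seeded generator of ChEMBL-like synthetic corpora.
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
    jsonlite,
    kernlab,
    Matrix,
    purrr,
    randomForest,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    ChemmineOB,
    ChemmineR,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
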