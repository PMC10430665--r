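Package: a2ascreen
Title: Structure-Based Antagonist Triage for the Adenosine A2A Receptor
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A decision pipeline for GPCR virtual-screening campaigns,
    developed around the adenosine A2A receptor. Per-residue eight-bit
    protein-ligand interaction fingerprints (PLIF) and hashed circular
    (Morgan/ECFP4) chemical fingerprints feed random-forest
    agonist/antagonist classifiers with grouped stratified
    cross-validation and Shapley (TreeSHAP) feature attribution. The
    classifier probability filter is combined with an affinity cutoff,
    Tanimoto-distance hierarchical clustering with silhouette model
    selection, a kinetic Gs/cAMP dose-response simulation with Hill-curve
    summaries, and a maximum-Tanimoto chemotype-novelty score to select
    and rank candidate antagonists. Synthetic generators build pocket
    geometries, two-class ligand libraries and planted fingerprint
    partitions so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    ChemmineR,
    ChemmineOB,
    randomForest,
    cluster,
    deSolve,
    minpack.lm,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
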