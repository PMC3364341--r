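Package: dtiforge
Title: Chemogenomic Drug-Target Interaction Prediction
Version: 0.2.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end chemogenomic framework for predicting drug-target
    interactions from chemical structure and protein sequence. Proteins are
    encoded by seven families of sequence-derived structural and
    physicochemical descriptors (amino-acid and dipeptide composition,
    autocorrelation, composition/transition/distribution, quasi-sequence-order,
    amphiphilic pseudo-amino-acid composition, and averaged residue
    properties); small molecules by an open battery of 2D descriptors.
    Labelled drug-target pair vectors are assembled by concatenation with
    negatives sampled from the non-interaction space, and models are evaluated
    under general and cold-start (new-drug/new-target) splits. Random Forest
    and RBF-SVM classifiers produce per-pair binding scores, which feed a
    comprehensive screening workflow with bipartite interaction-network
    topology analysis and hierarchical clustering of predicted ligands. A
    seeded synthetic-catalog generator with a planted interaction rule makes
    every stage testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    methods,
    randomForest,
    e1071,
    igraph,
    ape,
    yaml,
    jsonlite,
    Biostrings,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
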