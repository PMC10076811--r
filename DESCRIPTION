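Package: phagehost
Title: Ensemble Prediction of Bacterial Hosts for Bacteriophages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts the bacterial host of a bacteriophage from genome
    sequences by combining alignment-based predictors (phage-phage and
    phage-host nucleotide similarity, CRISPR spacer matching), an
    alignment-free k-mer composition classifier, a hybrid
    similarity-weighted score, and a staged decision cascade.
    Includes reference-database management, CRISPR array detection,
    taxonomic-rank evaluation (accuracy, coverage, probability of correct
    prediction from genus to phylum), and a deterministic synthetic
    benchmark generator with planted homology, mutations, and CRISPR
    protospacers so the whole pipeline can be exercised offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    glmnet,
    e1071,
    rpart,
    nnet,
    randomForest,
    xgboost,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
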