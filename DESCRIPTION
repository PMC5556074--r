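Package: hotspotr
Title: Hot-Spot Classification at Protein-Protein Interfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies and classifies interfacial residues of protein-protein
    complexes as binding Hot-Spots (alanine-scanning ddG >= 2 kcal/mol) or
    Null-Spots. Computes solvent-accessible-surface-area, contact and
    interface-composition features from PDB structures, plus sequence
    descriptors (amino-acid composition, pseudo amino-acid composition,
    amphiphilic pseudo amino-acid composition, substitution-matrix scale
    covariances, and position-specific scoring matrix profiles). Provides the
    full training methodology: z-score/PCA preprocessing with class
    resampling, capability-tag clustering of candidate classifiers by Jaccard
    distance, repeated stratified cross-validated benchmarking, MANOVA
    cluster comparison, and a stacked ensemble of per-cluster champion
    classifiers combined by a stepwise-selected logistic meta-model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils,
    MASS,
    class,
    e1071,
    glmnet,
    kernlab,
    nnet,
    randomForest,
    ranger,
    xgboost,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    withr
Config/testthat/edition: 3
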