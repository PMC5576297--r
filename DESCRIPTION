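Package: pssmrt
Title: DNA-Binding Residue Prediction with PSSM Relation Transformation Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Sequence-based prediction of DNA-binding residues from
    evolutionary profiles. Implements the PSSM Relation Transformation
    (PSSM-RT) encoding, which augments per-position conservation scores
    with pairwise and left/right cumulative relationships of normalized
    PSSM scores between a target residue and its sliding-window context,
    plus sequence and physicochemical feature blocks. Class imbalance
    between binding and non-binding residues is handled by an ensemble
    built from balanced negative-subset partitions, SVM and random-forest
    base predictors per feature block, diversity-based dynamic selection
    and majority voting. Includes interface-residue labeling from
    protein-DNA complex structures at a 3.5 Angstrom atom-distance
    cutoff, confusion-based evaluation metrics with ROC/AUC and k-fold
    cross-validation, discriminant-weight feature analysis, and
    seed-deterministic synthetic data generators for end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    e1071,
    ranger,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
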