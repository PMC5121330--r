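Package: nabind
Title: Two-Stage Prediction of Nucleic-Acid-Binding Residues and Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds labeled datasets of DNA- and RNA-binding residues from
    protein-nucleic-acid co-complex structures (heavy-atom contacts strictly
    below 5 Angstrom), encodes each residue as a 246-dimensional windowed
    feature vector from sequence and per-residue descriptor tracks, trains a
    per-residue random-forest classifier under homology-aware grouped
    cross-validation, aggregates residue score tracks into 15 protein-level
    distribution features, and trains a per-protein classifier whose
    fold models are combined by a two-of-three majority rule. Includes
    redundancy clustering, the full evaluation suite (precision/recall,
    ROC, PRC, AUC, MCC), and seeded synthetic-data generators (toy
    co-complex structures, synthetic alignments, planted-signal datasets)
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    Biostrings,
    bio3d,
    ranger,
    yaml,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
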