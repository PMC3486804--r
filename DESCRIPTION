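Package: hspkernel
Title: Hash Subgraph Pairwise Graph Kernel for Drug-Drug Interaction
    Extraction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts drug-drug interactions from dependency-parsed
    sentences with the hash subgraph pairwise (HSP) graph kernel. Builds a
    two-component sentence graph (dependency structure plus linear token
    order) with blinded candidate entities, prunes it to the syntactic
    neighborhood of the candidate pair, computes hierarchical neighborhood
    hash labels by iterated bit rotation and XOR, accumulates subgraph-pair
    features weighted by a Neumann walk series, and classifies candidate
    pairs with a maximum-margin classifier on the precomputed kernel
    matrix. Includes readers for DDI-corpus-style XML and CoNLL-style
    dependency parses, seeded synthetic-corpus generators, evaluation
    metrics (F-score, accuracy, MCC, rank-statistic AUC) and document-level
    cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
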