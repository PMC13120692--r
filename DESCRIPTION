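Package: hiergo
Title: Hierarchical Ontology-Aware Protein Function Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Ontology-aware multi-label protein function prediction with
    zero-shot generalization to unseen Gene Ontology (GO) terms. Provides an
    OBO parser and GO DAG utilities (ancestor closure, true-path-rule
    propagation, deterministic topological orderings), structure-recovering
    GO term embeddings learned from frozen definition-text embeddings via a
    multi-task linear autoencoder, a transformer encoder-decoder that decodes
    GO terms in topological order with causal self-attention and
    cross-attention to residue embeddings, CAFA-style evaluation (Fmax,
    macro/micro AUPR, term-centric AUC), attention-rollout residue
    attribution, and a seeded synthetic-data generator with planted
    sequence motifs for download-free end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
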