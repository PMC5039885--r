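Package: fpmpn
Title: Protein Function Prediction on Multilayer Protein Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts Gene Ontology annotations for unannotated proteins by
    transferring functions from weighted neighbours across a multilayer protein
    network. Three layers are built from standard inputs: a shared-complex
    layer from a protein-complex catalog, a shared-domain layer from
    protein-to-Pfam assignments, and a physical-interaction layer from a
    protein-protein interaction edge list weighted by an edge clustering
    coefficient. Layers are visited in a fixed access order with geometrically
    decaying importance coefficients; per-layer neighbour scores are combined
    into a composite score and the top-ranked terms are selected using the
    annotation count of the closest annotated neighbour. Includes per-layer
    neighbour-counting baselines, a data-driven layer-ordering procedure,
    leave-one-out and k-fold cross-validation with precision/recall/F-measure,
    coverage rate, precision-recall curves with AUC and FP/TP curve summaries,
    and a deterministic synthetic-data generator with planted function
    structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    Matrix,
    methods,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
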