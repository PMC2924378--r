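Package: slimfilter
Title: Function-Based Filtering of Short Linear Motif Predictions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reduces false-positive short linear motif (minimotif)
    predictions by requiring that the motif-bearing source protein and its
    putative target protein share a Gene Ontology term, or terms joined
    through a nearby common ancestor in the ontology graph. Provides an OBO
    ontology parser with common-ancestor edge distances, GAF annotation and
    accession-alias handling, degenerate consensus-pattern scanning with an
    expected-occurrence frequency score, either-or filter combination with
    an invert ("exclude") mode, and evaluation via sensitivity, selectivity,
    the discrimination ratio, trapezoidal ROC/AUC and rank-sum or
    permutation significance tests. A seeded synthetic-data generator
    emulates ontologies, annotations, sequences and positive/negative pair
    sets so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    igraph,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
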