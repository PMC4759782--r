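Package: molluscfam
Title: Comparative Gene-Family Analysis for Mollusc Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for comparative gene-family analysis of
    mollusc (and other multi-species) genome gene models: gene-model
    filtering with stage-by-stage retention accounting, reference ortholog
    family assignment plus de novo Markov clustering of an all-vs-all
    similarity graph, lineage-sharing classification of families,
    hypergeometric GO-term enrichment, tandem gene-array and homeobox
    cluster-layout detection, assembly summary statistics, and gene-tree
    annotation of lineage-specific expansions and supported ortholog
    pairs. Includes a synthetic three-genome generator with planted family
    structure so every stage can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    jsonlite,
    Matrix,
    igraph,
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
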