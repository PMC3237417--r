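Package: mirorigin
Title: Classification of MicroRNA Gene Origin Modes in Plant Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for classifying plant microRNA genes by
    their mode of origin: transposable-element related, pseudogene related,
    inverted duplication, tandem duplication, segmental duplication, or
    other. Includes hairpin secondary-structure validation with
    MIRcheck-style criteria, reverse-complement local-alignment detection of
    inverted duplications, collinear anchor chaining for segmental
    duplication blocks, mechanism sub-typing of de novo generated miRNA
    genes, a comparative feature panel for de novo versus conserved miRNA
    genes, Monte Carlo gene-set intersection tests, and a synthetic-genome
    generator with planted truth labels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    yaml,
    digest,
    withr,
    glmnet,
    stats,
    utils,
    tools,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
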