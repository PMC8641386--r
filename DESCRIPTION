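Package: annocure
Title: Evidence-Driven Quality Control and Curation of Plant Gene Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Toolkit for post-prediction curation of plant genome annotations:
    structural validation of gene models (interrupted open reading frames,
    formatting errors), evidence-driven repair of incorrectly split and merged
    gene predictions, rescue of prior-version genes supported by protein
    evidence, transposable-element gene labeling by repeat coverage and Pfam
    domains, systematic locus nomenclature, Astalavista-style classification of
    elementary alternative-splicing events, and cross-version gene
    correspondence mapping. Ships a deterministic synthetic-data generator that
    emits genomes, clean and corrupted annotations, evidence tracks, repeats
    and isoform sets with known ground truth, so the whole workflow is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    S4Vectors,
    stringr,
    tibble,
    tidyr
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
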