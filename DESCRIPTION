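Package: reglinkmap
Title: Cross-Species Mapping and Expression-Based Confirmation of
    Transcriptional Regulatory Links
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Maps a transcriptional regulatory network from a model (source)
    genome onto a non-model (target) genome. Transcription factors are mapped
    by local sequence similarity optionally refined by protein family or
    subfamily concordance; target genes are mapped by similarity and by
    scanning IUPAC consensus binding-site motifs; mapped elements are
    integrated into signed predicted regulatory links, which are then
    confirmed against ternary gene-expression calls with a counting rule
    engine and evaluated against gold-standard sets with confusion-matrix
    statistics. Includes a deterministic synthetic-scenario generator with a
    known truth table so the full pipeline is testable without external data
    or aligners.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
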