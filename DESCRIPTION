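Package: boundalign
Title: Alignment of Exon Boundaries with Protein Domain and Disorder Boundaries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tests whether the boundaries of exons align with the boundaries of
    protein domains and of intrinsically disordered regions more often than
    expected by chance, across many genomes. Maps splice junctions from genomic
    CDS coordinates to protein residue positions, builds one-residue boundary
    windows around domain and disorder assignments, computes observed and
    expected window-hit counts under a uniform-placement null, aggregates per
    genome with chi-square significance, classifies proteins as carrying novel
    or shared domain architectures, and compares alignment in new versus old
    proteins with a bootstrap partition test. Includes a synthetic multi-genome
    generator (GTF plus domain, disorder and label tables) with a tunable
    planted enrichment of splice junctions at domain boundaries, so the whole
    pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    rtracklayer,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
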