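Package: famtrace
Title: Gene Family Evolution by Locus Tracing, Intron Phylogenetics and
    Clone-End Scaffolding
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Comparative-genomics toolkit for tracing the origin and evolution
    of a gene family across sequenced genomes. Classifies candidate homologs
    from domain composition and similarity-hit evidence, links and orients
    assembly contigs from paired clone-end hits, assigns family members to
    named loci via flanking anchor genes and reconstructs ancestral locus
    gain/loss by Dollo parsimony, maps coding-sequence intron positions and
    phases onto protein alignments to infer intron gain and loss, and checks
    concordance between phylogenetic clades and syntenic loci. Ships a
    genome-evolution simulator (duplication, loss, pseudogenization, intron
    gain/loss, scaffold fragmentation with clone-end pairs) with a full
    ground-truth event log so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    rtracklayer,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
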