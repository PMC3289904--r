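Package: hgtsignal
Title: Compositional and Phylogenetic Signatures of Horizontally Acquired
    Bacterial Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects and characterises ameliorated horizontally transferred
    genes on annotated bacterial contigs. Provides whole-sequence and
    codon-position GC profiling (GC1/GC2/GC3) with sliding windows,
    compositional outlier scoring of genes against their contig, a
    stop-codon usage census and its rank correlation with genomic GC,
    Kimura-corrected protein distances with neighbor-joining tree
    construction, column-resampling bootstrap support and outgroup rooting,
    anchored gene-neighborhood synteny comparison with gene-pair orientation
    classification, and fully seeded synthetic-data generators (annotated
    contigs with controlled codon-position composition, foreign-gene
    insertions, multi-genome stop-codon panels, protein families evolved on
    a known tree) so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
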