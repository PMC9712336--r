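Package: mucintr
Title: Resolving Tandem-Repeat Mucin Domain Exons from SMRT Long Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the tandem-repeat (PTS) mucin domain exon of
    gel-forming mucins (MUC2-like loci) from noisy single-molecule long
    reads. Reads spanning the repeat exon are recruited with flanking-intron
    and CysD-island anchors, multiply aligned with zero gap penalties,
    collapsed to a per-column majority consensus, and polished by
    translation-guided correction of homopolymer frameshifts. The polished
    domain is decomposed into repeat units, two individuals' domains are
    compared for SNPs and repeat copy-number events, and repeat-number
    differences are estimated from single-T nucleotide counts. A seeded
    locus and read simulator makes every stage testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    BiocGenerics,
    S4Vectors,
    IRanges,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
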