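Package: intronmatch
Title: Optimal Matched Segments Between Post-Spliced Introns and Their
    Mature mRNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Screens for sequence-level association between post-spliced
    introns and their own mature mRNAs. Each intron is complemented and
    locally aligned against its mRNA under either the classic EDNAFULL
    substitution matrix (SW scheme) or a binding-free-energy-weighted
    scheme (BFE scheme, +5 for A:T pairs, +6 for G:C pairs, -4 for
    mismatches), yielding one optimal matched segment (OMS) per
    intron-mRNA pair. From the OMS set the package computes relative
    matched frequency (RF) profiles over length-normalized mRNAs and
    around functional sites (start codon, stop codon, exon-exon
    junctions), OMS sequence statistics (match rate, length, G+C,
    second-order informational redundancy D2), and a
    composition-constrained shuffle null. A synthetic gene-model
    generator with planted complementary segments makes every stage
    testable without external genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
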