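Package: pirnadev
Title: Small-RNA Silencing Signatures and Clonal Memory of piRNA-Mediated
    Repression in Developing Germlines
Version: 1.0.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for profiling PIWI-interacting RNA (piRNA) populations in
    small-RNA sequencing libraries and for testing whether piRNA-mediated
    silencing states are clonally inherited during germline development.
    Covers adapter trimming and length filtering of small-RNA reads,
    exhaustive placement of reads on compact reference loci with
    multi-mapping weight apportionment, library annotation and effective-depth
    or miRNA-based normalization, locus-level silencing signatures (stranded
    coverage, size distributions, 1U bias, ping-pong 5' overlap histograms),
    transposon-level antisense RPKM and germline-knockdown comparisons, and a
    clonal-memory analysis: clone homogeneity classification, a closed-form
    probability under the plastic-repression null, and lineage simulation of
    primordial germ cells and ovarioles. A synthetic-data generator produces
    small-RNA libraries and gonad clone tables with the statistical structure
    the analyses assume, so the whole pipeline is testable without external
    sequencing data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo: Rcpp
Imports:
    Rcpp,
    Biostrings,
    Rsamtools,
    S4Vectors,
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
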