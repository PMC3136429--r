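Package: mrchip
Title: Multi-Read Allocation and Peak Detection for ChIP-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Utilities for incorporating multi-mapping reads into ChIP-seq
    peak detection. Implements iterative probabilistic allocation of
    multi-reads across their candidate alignments using a Fenwick-tree
    count index, nucleotide- and bin-level genome mappability (uni-read and
    multi-read aware definitions, with fragment extension) and GC content,
    fragment-extended bin-level count construction, peak calling by a
    conditional binomial test and by a two-component negative-binomial
    mixture with covariate-adjusted background, comparison and
    similarity-based classification of peaks found only with multi-reads,
    saturation analysis, peak annotation against promoters, genic windows
    and segmental duplications, consensus-motif counting with a
    matched-null enrichment test, and TSS aggregation profiles. Includes a
    synthetic-data module (genomes with segmental duplications, planted
    binding peaks, strand-aware single-end tags, and a toy exact
    multi-mapper) so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    Biostrings,
    Rsamtools,
    rtracklayer,
    MASS,
    splines
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
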