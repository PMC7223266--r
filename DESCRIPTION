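Package: graphbwt
Title: Run-Length Encoded FM-Index of Haplotype Paths over Variation Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the Graph BWT (GBWT), a run-length encoded,
    record-partitioned FM-index of haplotype paths over bidirected variation
    graphs. Supports incremental (BCR-style) construction, merging and path
    removal, find/locate/extract queries, bidirectional (FMD-style) search,
    derivation of haplotype paths from a reference FASTA plus a phased VCF
    with overlap resolution and phase breaks, and haplotype-aware graph
    simplification that unfolds haplotype-supported paths through pruned
    regions so that no haplotype k-mer is lost. Includes GFA1 input/output,
    a synthetic fixture generator and a brute-force reverse-prefix-sorting
    oracle used as ground truth in the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    Biostrings,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
RoxygenNote: 7.3.3
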