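Package: binflow
Title: Transcript Assembly from Spliced Alignments via Exon-Bin Graphs and Network Flows
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reference-guided transcript assembly and quantification from
    coordinate-sorted spliced paired-end alignments. Reads are decomposed into
    exon-range bins, consolidated in an overlap/containment graph, and compacted
    into a generalized splice graph whose edges carry maximal exon chains.
    Coverage is denoised by a convex-cost minimum-cost network flow, ambiguous
    nodes are resolved with read phasing evidence via a two-step linear program,
    and residual flow is decomposed into quantified transcript models written as
    GTF. Includes a deterministic simulator of synthetic loci (transcript
    structures, paired-end read sampling, SAM and truth GTF emission) so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    GenomicAlignments,
    Rsamtools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
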