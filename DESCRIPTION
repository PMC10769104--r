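Package: irtoolkit
Title: Intron-Retention Detection and Structural Comparison of Transcript
    Annotations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with transcript annotations and assemblies in
    GTF format. Classifies assembled transcripts with (partial or entire)
    intron retention using abundance-gated structural criteria and partitions
    an assembly into flagged and retained subsets. Computes structural
    similarity between two annotations with Jaccard indices at the
    intron-exon boundary, junction and intron-chain levels, builds gene
    correspondences from shared boundaries, and evaluates assemblies against
    reference annotations via exact intron-chain matching, precision,
    adjusted precision, biotype stratification, union/intersection reference
    construction and threshold sweeps. Includes deterministic synthetic-data
    generators so the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    stats
Suggests:
    jsonlite,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
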