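Package: TxConsolidate
Title: Two-Tiered Consolidation and Evaluation of Hybrid Transcriptome Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Consolidates candidate transcript sets from reference-guided and
    de novo assembly branches into a deduplicated, filtered, merged and
    clustered final transcript set, and scores any transcript set against a
    reference proteome. Implements mapping-coverage, canonical splice-site and
    longest-ORF locus filters for genome-anchored transcript models; ungapped
    containment redundancy removal, k-mer single-linkage clustering and
    forward-only overlap-consensus re-assembly for de novo transcripts;
    cross-branch merging; and evaluation statistics including the u80
    reference-proteome completeness metric with gap classes, a
    correct/incomplete/false transcript classifier, a protein presence test and
    a cluster-versus-locus paralog contingency table. A seeded simulator of toy
    genomes, isoforms and corrupted transcript sets with truth labels supports
    fully self-contained testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
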