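Package: satanchor
Title: Satellite-Anchored Mate-Pair Localization of Tandem-Repeat RNA
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Locates the genomic origins of satellite (tandem-repeat) RNA
    from paired-end RNA-seq. Reads carrying perfect tandem motif runs are
    classified, their uniquely mappable mates are assembled into contigs
    with a greedy overlap-layout-consensus assembler, contigs are placed
    on the genome by ungapped seed-and-extend alignment under a
    chance-expectation (e-value) filter, and origin loci are called by
    adjacency to annotated satellite blocks. Also provides a per-motif
    satellite expression screen over FASTQ, a fully seeded synthetic-data
    generator (planted satellite arrays, transcripts, paired-end reads
    with ground-truth manifests), and the small quantification statistics
    used alongside the mapping pipeline: pooled phenotype proportions,
    Welch two-sample t tests, viability ratios and fertility summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    methods,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
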