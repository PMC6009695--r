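Package: ribostitch
Title: Resolving Ribosomal RNA Operon Repeats in Short-Read Bacterial Assemblies
Version: 0.1.0
Authors@R:
    person("Ribostitch", "Developers", email = "ribostitch@example.org",
           role = c("aut", "cre"))
Description: Reference-guided resolution of ribosomal RNA operon (rDNA) repeats in
    prokaryotic short-read assemblies. Reads are baited onto the rDNA regions of a
    related reference genome, iteratively subassembled into per-operon
    pseudocontigs, and the pseudocontigs are threaded through the read de Bruijn
    graph to place each near-identical rDNA copy in its correct genomic context
    ("de fere novo" assembly). Includes rRNA annotation normalisation, Jenks
    natural-breaks operon clustering, a built-in seed-and-extend read mapper, a
    single-k de Bruijn assembler with trusted-contig threading, flank-synteny
    junction scoring, alignment-column entropy and coverage diagnostics, and
    seed-deterministic simulators for genomes, reference mutation models and
    paired-end reads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    BiocGenerics,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    methods,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
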