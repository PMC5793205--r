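Package: famscan
Title: Genome-Wide Identification and Characterization of Transcription-Factor Gene Families
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for genome-wide analysis of a protein domain
    defined gene family (modelled on plant basic/helix-loop-helix, bHLH,
    transcription factors). Screens a proteome with a log-odds domain profile
    built from a seed alignment, keeps representative transcripts carrying a
    complete domain and names members by chromosomal order; characterizes
    members by length, molecular weight, isoelectric point, intron count and
    intron phase, and conserved-motif architecture; calls duplicated gene
    pairs by global-alignment coverage and similarity and classifies tandem
    clusters and segmental pairs; builds Neighbor-joining trees from
    Poisson-corrected pairwise-deletion distances with bootstrap supports and
    assigns subfamilies against labelled references; and analyses expression
    from FPKM matrices (grand-mean equalization, log2, low-expression
    filtering, average-linkage clustering) and qPCR Cq tables (2^-dCt and
    2^-ddCt). A synthetic-data generator plants ground truth for every stage
    so the whole pipeline can be exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    grDevices,
    jsonlite,
    methods,
    Rcpp,
    rtracklayer,
    S4Vectors,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    pheatmap,
    phangorn,
    phytools,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
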