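Package: indelrdd
Title: Detection and False-Positive Filtering of Indel RNA-DNA Differences
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An end-to-end pipeline for detecting single-base insertion and
    deletion differences between RNA-seq reads and a matching diploid genome,
    and for classifying the candidates that survive initial quality filtering
    into the four artifact classes that dominate such call sets: heterozygous
    (paternal) alleles, splice-junction misalignments, paralog cross-mappings,
    and known genomic indel variants. Includes a synthetic diploid genome and
    spliced-read simulator that plants each artifact mechanism with truth
    labels, a seed-and-extend gapped short-read aligner, a pileup-based indel
    caller with configurable quality filters, and a sensitivity analysis that
    measures recovery of haplotype indel differences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
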