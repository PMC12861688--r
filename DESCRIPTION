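Package: fragmeth
Title: Fragment-Level Analysis of DNA Methylation Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A toolkit for fragment-level analysis of DNA methylation
    sequencing data (WGBS, EM-seq, and base-modification-tagged long
    reads). Builds a genome-wide CpG coordinate system from a reference
    FASTA; converts aligned reads into a compact fragment-pattern (PAT)
    representation and a per-CpG counts (BETA) representation; segments
    the genome into blocks of homogeneous methylation by dynamic
    programming under a Beta-Bernoulli model; classifies fragments as
    mostly-methylated, mostly-unmethylated or mixed; detects
    allele-specific (bimodal) methylation with a two-component mixture
    fitted by expectation-maximization and a likelihood-ratio test;
    finds and ranks group-specific differentially methylated blocks; and
    renders fragment stacks and per-CpG methylation heatmaps in the
    terminal. Includes a simulator of CpG-bearing genomes and converted
    reads with known ground truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rsamtools,
    GenomicRanges,
    GenomicAlignments,
    IRanges,
    data.table,
    stats,
    utils
Suggests:
    optparse,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
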