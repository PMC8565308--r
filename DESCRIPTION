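Package: rimsseq
Title: Methylase Specificity Discovery from Deamination Signatures in
    Paired-End Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of RIMS-seq experiments, in which limited heat-alkaline
    deamination of a standard Illumina library converts 5-methylcytosine to
    thymine on the first read of each pair while deaminated unmethylated
    cytosines block amplification.  The package detects the resulting
    read-pair-specific C-to-T substitution signature from paired-end
    alignments, discovers m5C methyltransferase recognition motifs de novo as
    degenerate IUPAC strings with base-resolution assignment of the methylated
    cytosine, estimates the achieved deamination rate from fully methylated
    spike-in controls, computes substitution spectra, context tables,
    two-sample sequence logos and community abundances, and simulates
    paired-end libraries carrying the documented damage signature so the whole
    pipeline can be validated without sequencing data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    Rsamtools,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
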