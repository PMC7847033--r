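Package: xenosplit
Title: Species Deconvolution of Droplet Single-Cell Sequencing Reads from
    Xenograft Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Pre-processing of paired FASTQ files from droplet-based
    single-cell experiments on xenograft samples (e.g. patient-derived
    xenografts), where reads originate from both the grafted species and
    the host animal. Builds a dual-species canonical k-mer index from two
    reference sequences, classifies every cDNA read as graft-specific,
    host-specific, both, neither, or ambiguous, tabulates graft and host
    read fractions per cellular barcode, selects barcode subsets by a
    closed interval on the host-read fraction, and writes filtered paired
    FASTQ files ready for standard single-cell pipelines. Includes a
    ground-truth simulator for mixed-species experiments with doublets and
    sequencing errors, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    tools
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
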