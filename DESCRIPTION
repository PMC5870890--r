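Package: crrnaprofiler
Title: CRISPR RNA 3'-End Profiling from Multiplexed Small RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Processing pipeline for strand-specific small RNA sequencing
    libraries built with a pre-adenylated 3' adapter carrying a random
    hexamer unique molecular identifier (UMI), as used to assay CRISPR RNA
    (crRNA) biogenesis in bacteria. Demultiplexes raw single-end Illumina
    reads by exact index-read comparison, locates and removes the 3'
    adapter to expose the captured RNA 3' end, collapses PCR duplicates by
    exact insert+UMI identity, identifies crRNA-derived reads by
    repeat-anchored filtering (seed match, minimum repeat length or
    spacer-repeat junction rescue, left-anchored fidelity), counts
    reference-gene reads by 25-nt substring containment, and renders the
    per-base distribution of crRNA 3' ends along the CRISPR repeat
    normalized to the reference gene. Includes a synthetic sequencing-run
    simulator that reproduces the protocol's molecular read structure with
    ground truth, so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    ggplot2,
    stats,
    tibble,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
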