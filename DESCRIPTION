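Package: plasmidcons
Title: Plasmid Sequence Verification from Nanopore Long Reads by Pileup
    Consensus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Verifies the sequence identity of a linearized plasmid from
    Oxford-Nanopore-style long reads. Reads are quality- and
    length-filtered, classified by strand and pseudopaired against the
    expected reference, and piled up over a draft consensus built from
    the reads themselves. Each consensus base is called under explicit
    criteria (top base at least 5x the second, top coverage at least 10%
    of the maximum) with per-base counts, confidence and signal-to-noise
    reported, and the consensus is generated twice (against the draft and
    its reverse complement) so that alignment artefacts near homopolymers
    cannot hide a variant. The final report compares both passes to the
    expected sequence, types discrepancies (SNV, insertion, deletion, N),
    flags contamination through the pseudopairing rate, and a mixture
    scan measures the minimum subclonal variant fraction the criteria can
    detect. A synthetic read simulator with strand-specific errors,
    homopolymer run-length undercall and template mixtures makes every
    stage testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
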