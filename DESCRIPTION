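Package: ivtcontrol
Title: IVT Negative Controls for Nanopore Direct RNA Sequencing Mismatch Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and using in vitro transcribed (IVT) unmodified
    transcriptome negative controls in nanopore direct RNA sequencing (DRS)
    modification studies. Converts aligned long reads into per-position
    nucleotide/deletion pileups, flags reference mismatches by occurrence
    fraction with a multi-threshold sweep and BED track emission, curates
    low-confidence 9-mer contexts from base qualities, partitions mismatches
    into known-variant / low-confidence / novel bins, pools samples and
    tabulates cross-sample overlap, computes gene-coverage saturation by
    round-robin subsampling and naive TPM abundance correlation, and applies
    a decision procedure that nominates candidate RNA-modification sites
    where biological reads mismatch the reference but the IVT control does
    not. Includes a fully specified read simulator so every stage is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    GenomicRanges,
    IRanges,
    Rsamtools,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    methods,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    vcfR,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
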