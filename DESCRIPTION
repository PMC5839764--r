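Package: shmatlas
Title: Somatic Hypermutation Atlas of AID Off-Target Mutations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for activation-induced deaminase (AID)
    off-target mutagenesis from targeted deep-sequencing base counts.
    Scans capture regions for AID hotspot motifs (WRC, WRCY, AGCTNT) in the
    deaminated-cytosine frame, masks germline SNPs, computes per-region
    mutation-frequency summaries, calls AID target regions by a one-tailed
    Fisher contrast against AID-null controls with Benjamini-Hochberg FDR
    control, analyzes the sequence context of mutated cytosines, compares
    DNA-repair genotypes, and predicts gene mutability from transcriptional
    features with a conditional-inference classification tree. A synthetic
    data generator emulates genotype-specific deamination and repair
    spectra, sequencing error, heterozygous SNPs and feature tables so
    every stage is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    Biostrings,
    GenomicRanges,
    IRanges,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
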