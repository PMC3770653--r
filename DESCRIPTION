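Package: rearrangemap
Title: Detection, Fine-Mapping and Mechanistic Classification of Large
    Genomic Rearrangements
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A desk-scale pipeline for characterizing large genomic
    rearrangements (LGRs) at a gene locus, modelled on the workflow used for
    MSH2 in Lynch syndrome diagnostics: MLPA dosage-quotient screening,
    array-CGH segmentation with consecutive-probe filtering, split-read
    breakpoint mapping from amplicon reads, junction microhomology and
    insertion analysis, repeat-element overlap, NAHR/NHEJ mechanism
    classification, HGVS-style nomenclature, and cohort genotype-phenotype
    summaries.  A synthetic-data module generates repeat-dense reference
    loci, rearranged alleles with known truth, reads, and dosage tables so
    every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
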