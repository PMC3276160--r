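Package: aseChip
Title: Design and Analysis of Allele-Specific Expression SNP Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for rule-based design and statistical analysis of
    allele-specific expression (ASE) microarrays in Drosophila. Identifies
    biallelic SNPs from multiple sequence alignments and emits 24-probe
    allele-discriminating probe sets; performs GC-bin background correction,
    detection-above-background (DABG) calls and log-scale probe-set
    summarization; tests sex-biased expression, sex-specific isoform usage
    (heteroscedastic exon-by-sex interaction), rank-based genotype calls
    and allelic imbalance against genomic-DNA hybridization controls, with
    false-discovery-rate correction throughout. Includes a synthetic-data
    generator with known truth so every pipeline stage is testable without
    array hybridizations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Biostrings,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    MASS,
    car
Config/testthat/edition: 3
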