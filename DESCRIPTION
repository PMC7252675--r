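Package: recessivescan
Title: Haplotype-Based Mapping of Recessive Loci for Semen Quality and Bull Fertility
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for mapping recessive quantitative trait loci
    from routinely recorded artificial-insemination data: filtering of repeated
    ejaculate records, pedigree-based EM/AI-REML estimation of heritability and
    repeatability under a repeated-records animal model, sliding-window
    haplotype association testing under additive, dominant and recessive
    inheritance with genomic-control diagnostics, shared-autozygosity
    fine-mapping among homozygous haplotype carriers, allele-frequency
    filtration of sequence variants for compatibility with recessive
    inheritance, and detection of variant-activated cryptic splice donors with
    junction-read tallies. A seeded synthetic-data generator reproduces the
    statistical structure these analyses assume, so every stage is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stats,
    utils,
    methods,
    Matrix,
    jsonlite,
    yaml,
    ggplot2,
    generics,
    vcfR,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    seqinr
Config/testthat/edition: 3
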