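Package: fmscan
Title: Population-Genomic Inference of the Chicken Fibromelanosis Structural Allele
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for resolving the internal
    arrangement of the chicken fibromelanosis (FM) structural allele from
    short-read population data mapped to a collapsed (single-copy) reference.
    Provides a synthetic-data generator for populations segregating candidate
    duplication/inversion architectures of the FM locus, an observation model
    for collapsed-reference depth and genotype signals, copy-number genotyping
    from relative sequencing depth, windowed nucleotide diversity and
    Weir-Cockerham FST scans with genome-background Z tests and
    Benjamini-Hochberg FDR, allele-frequency "bubble" and fixed-heterozygosity
    analysis with breakpoint detection, linkage-disequilibrium retention and
    block-boundary detection, neighbor-joining trees on SNP distances, and a
    signature-matching step that calls the generating configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    ape,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
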