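Package: herdgen
Title: Population Genomics of Small Livestock Herds from SNP-Array Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for conservation-genomics analysis of SNP-array genotypes
    from small or endangered livestock populations. Reads and writes PLINK
    text and binary genotype files, performs SNP and sample quality control
    with exact Hardy-Weinberg testing, detects parent-offspring pairs by
    genomic non-exclusion, detects runs of homozygosity (ROH) with a
    sliding-window scan and computes the genomic inbreeding coefficient
    F_ROH, estimates historical effective population size from binned
    linkage disequilibrium, and scans for selection signatures with a
    composite of F_ST, allele-frequency change and cross-population extended
    haplotype homozygosity. Includes a diploid Wright-Fisher forward
    simulator with recombination, selective sweeps, planted relatives and
    planted autozygosity so every stage can be validated against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
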