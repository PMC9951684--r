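Package: rohdiv
Title: Runs of Homozygosity, Diversity Partitioning and Conservation
    Priority for Multi-Breed SNP Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genomic conservation genetics of livestock breeds
    genotyped on dense SNP arrays. Reads PLINK text and binary genotype
    files, applies call-rate quality control and windowed LD pruning,
    computes molecular coancestry and Nei minimum distances, partitions
    gene diversity (HT = HS + DG) and rarefied allelic diversity
    (AT = AS + DA), ranks breeds by leave-one-out contributions, and
    optimizes the breed composition of a synthetic conservation pool.
    Detects runs of homozygosity (ROH) per individual under explicit
    length, SNP-count, density and gap constraints, summarizes them per
    breed, calls population-level ROH islands, intersects islands with
    gene/QTL interval tables, and estimates LD decay together with a
    Sved-inversion effective population size trajectory. A seeded
    Balding-Nichols simulator with autozygous-tract mosaics provides
    ground-truth datasets for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
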