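Package: boargen
Title: Population-Genomic Analysis of Wild Boar SNP-Array Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for continent-scale population-genomic analysis of
    SNP-array genotypes of European wild boar (Sus scrofa) and related
    study systems. Implements quality control of PLINK PED/MAP genotype
    panels (call rate, minor allele frequency, windowed LD pruning,
    method-of-moments identity-by-descent relatedness, intragenic-SNP
    exclusion), estimation of domestic-pig introgression by principal
    coordinates projection (F_hybrid) with pig-diagnostic-allele
    profiling, detection of runs of homozygosity and the genomic
    inbreeding coefficient F_ROH, and spatial genetic structure
    statistics: isolation-by-distance Mantel tests, ordination versus
    geography, multilocus heterozygosity with its linear model, and
    allele-frequency cline interpolation by ordinary kriging. A
    synthetic-data module generates Balding-Nichols structured
    populations, spatial allele-frequency clines, and gene-dropped
    hybrid and inbred pedigrees with known ancestry and autozygosity,
    so every stage of the pipeline can be exercised and calibrated
    without access to the original genotype deposition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    geosphere,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ape,
    vegan,
    jsonlite
Config/testthat/edition: 3
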