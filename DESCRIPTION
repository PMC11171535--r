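Package: introscan
Title: Genome-Wide Introgression Scans from Diploid Genotype Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and characterises between-population gene flow from
    diploid biallelic genotype panels. Implements pairwise FST (Hudson
    ratio-of-sums and Weir-Cockerham) with island-model gene-flow levels
    (Nm), genome-wide ABBA-BABA D statistics with weighted block-jackknife
    Z-scores, a windowed fd admixture-fraction scan with quantile outlier
    detection and signal merging, per-window validation statistics
    (nucleotide diversity, dxy, Tajima's D), and haplotype-level evidence
    (major-allele sharing matrices, extended haplotype homozygosity,
    bifurcation trees, LD r-squared). A bundled simulator generates phased
    four-population panels with Balding-Nichols drift and a planted
    introgression tract so every stage can be exercised against ground
    truth.
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
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
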