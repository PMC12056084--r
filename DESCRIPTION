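Package: trihybrid
Title: Triangle Plots and Hybrid Class Inference from Biallelic SNPs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies ancestry-informative markers (AIMs) between two
    parental groups from biallelic SNP genotypes, computes per-individual
    hybrid index and interclass heterozygosity, and draws triangle plots
    with the exact region permitted under Hardy-Weinberg equilibrium.
    Includes a cross-propagation engine for expected genotype frequencies
    in hybrid offspring (accounting for allele-frequency variance between
    parents), a seedable Mendelian simulator of hybrid classes with
    sequencing-depth and sample-size downsampling, and accuracy/precision
    error metrics for validating estimates against known hybrid classes.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    vcfR,
    ggplot2,
    optparse,
    rlang,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
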