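Package: invadepop
Title: Invasion Population Genomics: Structure, Introgression, Demography
    and Environmental Association
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of non-native (invasive) populations from
    reduced-representation SNP data: genotype quality control and
    Hardy-Weinberg imputation, principal-component and sparse-NMF admixture
    structure with cross-entropy model choice, Weir & Cockerham/Hill theta
    F_ST and hierarchical AMOVA, bootstrap drift trees, Patterson's D
    (ABBA-BABA) statistics with block-jackknife significance, folded
    site-frequency-spectrum demography (multi-epoch effective-size
    trajectories and nested two-population split models with
    Godambe-adjusted likelihood-ratio tests and chromosome-block bootstrap
    confidence intervals), and genotype-environment association with latent
    factor confounder correction, Storey q-values and an extreme
    allele-frequency-shift enrichment test. Includes a structured-coalescent
    simulator so every stage can be exercised against scenarios with known
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    ape,
    vcfR,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
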