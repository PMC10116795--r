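Package: krvgwas
Title: Covariate-Adjusted Kernel RV Association Testing for Microbiome GWAS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tests association between sets of genetic variants and
    community-level microbiome composition with the kernel RV (KRV)
    coefficient, a normalized Frobenius inner product between a genotype
    kernel and a microbiome kernel. Covariates such as population
    structure are removed from both kernels by projection, equivalent to
    residualizing every kernel principal component. P-values come from a
    Pearson Type III approximation to the permutation null, using exact
    first three permutation moments of the trace statistic, with a Monte
    Carlo permutation fallback. Includes beta-diversity machinery
    (rarefaction, Bray-Curtis, unweighted/weighted/generalized UniFrac,
    CLR and phylogenetic ILR transforms, Gower kernel construction with
    positive semi-definite correction), a two-stage gene-then-variant
    genome-wide scan with Bonferroni control, effective minor allele
    count filtering, genomic inflation diagnostics, kernel-PC taxa
    attribution, and a Dirichlet-multinomial simulation framework with
    two-population confounding and pleiotropic power scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    Matrix,
    Rcpp,
    stats,
    utils,
    vegan,
    vcfR
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    phyloseq,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
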