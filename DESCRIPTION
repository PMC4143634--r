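Package: rarewin
Title: Windowed Rare-Variant C-Alpha Testing with Stratification-Adjusted
    Permutation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Case-control rare-variant analysis for sequence data: a
    covariate-adjusted logistic scan selects index common variants, rare
    variants (minor allele frequency below 0.05) are collapsed in fixed
    windows around each index marker, and each window is tested with the
    C-alpha overdispersion statistic under a permutation null. Population
    stratification is handled by a biased-urn permutation scheme that
    relabels cases by exact sampling from the multivariate Fisher
    noncentral hypergeometric (conditional Bernoulli) distribution, with
    per-subject odds weights fitted from principal components of an
    LD-pruned genotype panel plus clinical covariates. Includes Hardy-
    Weinberg exact filtering, Fisher's exact comparison of in-gene versus
    not-in-gene windows, and a synthetic cohort generator (Balding-Nichols
    subpopulation model, mixed deleterious/protective/neutral rare-variant
    clusters, longitudinal binary phenotypes) for calibration and power
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    vcfR,
    rtracklayer,
    BiocGenerics,
    GenomeInfoDb
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
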