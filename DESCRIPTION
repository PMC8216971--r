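Package: provscan
Title: Environmental Association Analysis for Common-Garden Provenance Trials
Version: 0.1.0
Authors@R: person("Provenance", "Genomics", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end environmental association analysis (EAA) workflow
    for multi-provenance common-garden genomic studies. Provides strict SNP
    and sample quality-control filtering (minor allele frequency, exact
    Hardy-Weinberg tests, linkage-disequilibrium pruning, identity-by-descent
    kinship, heterozygosity deficit), climate-variable principal components,
    dendroclimatic trait derivation (spline detrending, robust chronologies,
    bootstrapped response functions), four genome-scan algorithms (hierarchical
    island-model FST outlier testing, latent factor mixed models,
    covariance-controlled allele-frequency Bayes factors, and an F-model
    comparison with environmental differentiation), consensus outlier
    identification, ancestry estimation, and redundancy analysis. A
    hierarchical island-model simulator with planted climate-adaptive loci,
    related pairs and inbred samples supplies ground truth for calibration
    and recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    VariantAnnotation,
    SummarizedExperiment,
    GenomeInfoDb,
    BiocGenerics,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
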