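Package: panelpop
Title: Population Structure Analysis of Biallelic SNP Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for population-genetic analysis of biallelic SNP panels
    typed on georeferenced collections of individuals, as used in marine
    fisheries stock identification. Provides Genepop and delimited-table
    input/output with sample- and SNP-level filters; per-collection
    diversity statistics (Ho, unbiased He, FIS), exact Hardy-Weinberg and
    genotypic linkage-disequilibrium tests with sequential Bonferroni
    correction; Weir-Cockerham theta (FST) with permutation testing and
    isolation-by-distance regression; dual FST-outlier detection (an
    FDist-style simulation envelope and a Bayesian F-model with
    reversible-jump MCMC) with a two-method consensus rule; Bayesian
    admixture clustering with correlated allele frequencies, replicate-run
    alignment, Evanno's delta-K and the Puechmaille cluster-number
    estimators; discriminant analysis of principal components; in-silico
    F1 hybrid simulation, credible-interval admixture classification and
    leave-one-out individual assignment; and a seeded synthetic genotype
    generator with truth tables for calibration and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    MASS,
    geosphere,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
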