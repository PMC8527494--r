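Package: wgrBayes
Title: Bayesian Whole-Genome Regression and GBLUP for Genomic Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Genomic prediction of quantitative traits from genome-wide SNP
    dosages. Implements the Bayesian alphabet of whole-genome regression
    models (BayesA, BayesB, BayesCpi, Bayesian LASSO) and GBLUP by
    single-site Gibbs sampling with residual updating, the VanRaden
    genomic relationship matrix, marker quality control (call rate, minor
    allele frequency, exact Hardy-Weinberg test, autosome filter) with
    frequency-based imputation of sporadic missing genotypes, posterior
    heritability, and k-fold cross-validated prediction accuracy. Includes
    a synthetic genotype/phenotype generator emulating a two-density SNP
    panel design with herd and sex fixed effects, plus PLINK text (PED/MAP)
    and dosage-matrix readers and writers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
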