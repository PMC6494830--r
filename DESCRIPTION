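Package: fieldevol
Title: Quantitative Analysis of Multi-Generation Field Evolutionary Experiments
Version: 0.1.0
Authors@R:
    person("Field Evolution Analytics Team", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing multi-generation field experimental-evolution
    studies of hybrid and control plant lineages. Implements conjugate Gibbs
    sampling for Bayesian linear trend models of standardized traits and
    fitness on generation, credible-interval support classification,
    hierarchical group contrasts, evolutionary rates in haldanes with pooled
    standard deviations, faster-lineage trait counts with one-degree-of-freedom
    chi-square comparisons, Lande-Arnold phenotypic selection analysis
    (selection differentials and gradients with bias-corrected-and-accelerated
    bootstrap intervals), adaptive-evolution classification, regression of
    evolutionary rate on phenotypic distance from a locally adapted reference,
    and detection of outside gene flow from backcross (BC1) allele catalogues
    applied to genotype matrices or VCF files. Includes seeded synthetic-data
    generators for phenotype tables and BC1-derived genotype matrices so that
    every analysis stage is testable without access to raw field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Rcpp,
    jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation,
    SummarizedExperiment,
    GenomicRanges
Config/testthat/edition: 3
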