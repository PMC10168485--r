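Package: presbyscan
Title: Phenotype Classification and Variant Association Scanning for
    Adult-Onset Hearing Loss Cohorts
Version: 0.1.0
Authors@R:
    person("Presbyscan", "Maintainers", email = "presbyscan@example.org",
           role = c("aut", "cre"))
Description: Tools for genotype-phenotype analysis of adult-onset hearing
    loss cohorts with pure-tone audiometry and exome-derived variant calls.
    Implements audiogram phenotype classification by non-negative
    decomposition into canonical metabolic and sensory presbyacusis
    profiles; consensus merging of genotype calls from multiple variant
    callers with quality-control filters (caller combination rules, excess
    heterozygosity, cohort allele-frequency anomalies, impact and minor
    allele frequency cutoffs, mitochondrial homoplasmy handling);
    gene-level variant-load outlier detection between phenotype groups via
    linear regression and an interquartile-distance residual rule with
    hypergeometric gene-set enrichment; and a per-variant audiometric
    threshold-difference scan with sex-preserving permutation testing. A
    synthetic-cohort generator reproduces the statistical structure of such
    studies so the full pipeline is testable without access-restricted
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
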