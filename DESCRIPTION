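Package: mbstrat
Title: Methylation-Based Subgroup Discovery and Risk Stratification for
    Childhood Medulloblastoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for unsupervised discovery of DNA-methylation subgroups of
    childhood medulloblastoma and for subgroup-dependent survival risk
    stratification. Implements bootstrapped non-negative matrix factorisation
    (NMF) consensus clustering of beta-value matrices with cophenetic model
    selection and confidence-thresholded subgroup assignment, non-negative
    least-squares projection of discovery metagenes onto independent cohorts,
    log-normal age modelling with density-intersection cutoff estimation,
    subgroup enrichment statistics, Kaplan-Meier/Cox survival machinery with
    time-dependent ROC evaluation and cross-validated forward covariate
    selection, and rule engines for four-tier clinical risk-stratification
    schemes. A synthetic-cohort generator emulating the statistical structure
    of methylation-profiled medulloblastoma cohorts makes the full pipeline
    testable end to end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    pracma,
    igraph
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
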