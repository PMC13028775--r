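Package: pgxburden
Title: Pharmacogenetic Burden Scoring and Statin Regimen Outcome Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for studying how cumulative pharmacogenetic (PGx) burden
    relates to statin regimen modification, intolerance, and adverse outcomes
    in coronary artery disease cohorts. Implements star-allele diplotype
    calling and function-phenotype assignment for SLCO1B1, dominant carrier
    coding for ABCG2 and CYP2C9, and a cumulative 0-4 PGx burden score with
    low/high dichotomization; ACC/AHA statin-intensity classification of
    pharmacy dispensing records with escalation/de-escalation detection,
    medication possession ratio adherence, and time-to-first-change; rule-based
    phenotyping of biochemical intolerance, myopathy, liver injury and
    composite adverse outcomes; and the association layer (contingency and
    logistic odds ratios, multinomial relative risk ratios, Cox/Kaplan-Meier
    persistence analysis, descriptive group comparisons). A seeded synthetic
    cohort generator emulates Hardy-Weinberg genotypes, dispensing
    trajectories and laboratory series with configurable effect sizes, so
    every stage is testable without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    nnet,
    data.table,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
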