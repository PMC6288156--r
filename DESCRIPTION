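Package: seedtrace
Title: Multifocal Prostate Cancer Progression and Seeding-Focus Signatures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers progression-associated genes from multifocal prostate
    tumour transcriptomes by a monotone selection rule across the
    adjacent-normal, primary-tumour and lymph-node-metastasis transitions,
    identifies the primary tumour focus most likely to have seeded the
    metastasis by hierarchical clustering of the most variable transcripts,
    and builds Cox-coefficient-weighted prognostic gene-expression scores
    evaluated against biochemical-recurrence survival with quantile cutoff
    transfer across cohorts. Includes negative-binomial differential
    expression (TMM normalisation, conditional dispersion estimation, exact
    test), self-contained Cox partial-likelihood, Kaplan-Meier, log-rank and
    Harrell concordance machinery, and a synthetic-data generator producing
    multifocal count matrices and survival cohorts with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    survival,
    edgeR,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
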