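Package: xsuppress
Title: X Chromosome Dosage Compensation and Germline X Suppression Analysis
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Pipeline for comparing X-linked and autosomal gene expression
    across tissues in species with heteromorphic sex chromosomes. Filters and
    replicate-averages FPKM expression tables, computes X-to-autosome median
    ratios with rank-sum comparisons, tests over- and under-representation of
    X-linked genes in cumulative expression categories against a genome-derived
    expected proportion, applies counterfactual dosage corrections, and
    aggregates hierarchical reporter-gene activity assays. Includes a seeded
    generative model of single-dose buffering and threshold-dependent X
    suppression in the male germline, used for parameter-recovery validation of
    every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    withr,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
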