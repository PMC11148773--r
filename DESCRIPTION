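Package: gicoreg
Title: Genome Instability Scoring and Kinase-Substrate Co-Regulation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end proteogenomic analysis of copy-number based genome
    instability. Computes the weighted genome instability index (wGII) from
    absolute copy-number segments, stratifies tumors into high/low instability
    groups by survival-driven cutoff optimization (Cox regression and log-rank
    testing), performs tumor-purity adjusted differential expression with
    empirical-Bayes moderated t-statistics, normalizes post-translational
    modification (PTM) intensities against parent protein abundance by
    residualization, and fits a two-dimensional empirical-Bayes mixture model
    of kinase-substrate co-regulation with a permutation null, posterior
    co-regulation probabilities and local false discovery rates. Includes a
    synthetic-data generator with known ground truth for validation, plus
    RNA-ISH H-score and N-glycoform classification utilities.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    survival,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
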