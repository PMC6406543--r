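Package: stratmir
Title: Gender-Stratified miRNA Differential Expression, qPCR Validation and
    Pathway Overlap Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reproducible pipeline for gender-stratified small-RNA
    differential-expression screens and their downstream interpretation.
    Implements moderated two-group t-tests with empirical-Bayes variance
    shrinkage on log-CPM counts, Benjamini-Hochberg false-discovery-rate
    control and effect-size filtering; chromosomal-band co-localization
    summaries for miRNA gene clusters; delta-delta-Ct relative
    quantification of RT-qPCR validation panels with two-way
    status-by-gender interaction ANOVA, assumption checks and Tukey HSD
    post-hoc contrasts; and network-based pathway enrichment
    (per-miRNA hypergeometric over-representation, Tukey-fence outlier
    selection of heavily co-targeted pathways, Jaccard-weighted overlap
    networks and subfamily over-representation). Seeded synthetic-data
    generators emulate the statistical structure of a two-cohort
    case-control miRNA study so the whole chain is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    car,
    yaml
Suggests:
    testthat (>= 3.0.0),
    limma,
    optparse,
    igraph,
    withr
Config/testthat/edition: 3
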