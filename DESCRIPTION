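Package: agomir
Title: Quantitative miRNA Microarrays, Argonaute Association Calling and
    Regulatory Network Assembly for AML Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of quantitative two-color miRNA microarrays
    in pediatric acute myeloid leukemia (AML) cohorts: spot-level quality
    filtering, spike-in calibration and normalization against a universal
    reference of synthetic miRNA oligonucleotides, absolute abundance
    estimation, differential expression between cytogenetic subtypes
    (Mann-Whitney U), nearest shrunken centroid subtype classification with
    repeated stratified cross-validation, complete-linkage clustering,
    probe-level mRNA summarization, Argonaute immunoprecipitation enrichment
    calling against isotype controls, consensus miRNA target-prediction
    intersection, hypergeometric pathway over-representation, and export of
    the miRNA-mRNA regulatory network. A synthetic-data generator emulating
    the full data structure makes every stage testable without external
    downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    ape,
    fgsea,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
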