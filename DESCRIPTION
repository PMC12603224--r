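Package: metaphen
Title: Metaphenomic Annotation and Probabilistic Diagnosis of Parkinsonian Disorders
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with metaphenomic annotations: a machine-readable
    format for clinicopathological cohort data in Parkinsonian disorders.
    Provides a phenotype-ontology layer (OBO and graph-JSON ingestion, is-a
    closure queries, count aggregation up the hierarchy), readers, validators
    and filters for cohort annotation files, pooling of per-cohort summaries
    into per-disease profiles with Gaussian onset and survival models,
    clinical-versus-pathological confusion matrices with sensitivity,
    specificity and balanced accuracy, likelihood-ratio screens over the
    phenotype ontology, a naive Bayesian differential-diagnosis calculator
    with screening projections and an inverse most-informative-observation
    query, and a synthetic literature-corpus simulator with parameter-recovery
    reporting.
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
    jsonlite,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
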