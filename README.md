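# metaphen

Metaphenomic annotation and probabilistic differential diagnosis of
Parkinsonian disorders.

## The problem

Clinical diagnosis of the Parkinsonian disorders — Parkinson's disease (PD)
and its atypical mimics, multiple system atrophy (MSA), progressive
supranuclear palsy (PSP), dementia with Lewy bodies (DLB) and corticobasal
degeneration (CBD) — is unreliable: even in expert centres a substantial
fraction of in-life diagnoses are contradicted at post-mortem, the diagnostic
gold standard. Decades of clinicopathological publications contain
gold-standard cases linked to in-life phenotypes, but the data are locked in
heterogeneous prose and tables.

`metaphen` provides the machinery to work with that literature
quantitatively. It defines a machine-readable *metaphenomic annotation*
format for published cohorts (pathological diagnosis, case counts,
onset/death/duration summaries, clinical-vs-pathological cross-tabs, and
phenotype observations as `(term, n_present, n_assessed)` counts against the
Human Phenotype Ontology), and builds on it:

- **ontology** — OBO / graph-JSON ingestion, is-a closure queries, and
  conservative aggregation of cohort counts up the hierarchy (e.g. subsuming
  rest, postural and action tremor into "tremor");
- **annotations** — readers, validators and filters for annotation corpora,
  with a strict missing-is-not-zero convention;
- **aggregation** — sample-size-weighted pooling of cohort summaries
  (equivalent to the statistics of the concatenated raw samples), Gaussian
  onset (30–100 y) and survival (0–30 y) models, age-conditional disease
  priors, and Kruskal–Wallis / Wilcoxon group comparisons;
- **accuracy** — clinical-vs-pathological confusion matrices, one-vs-rest
  sensitivity/specificity/balanced accuracy, misdiagnosis and
  missed-diagnosis rates, and accuracy-over-time series;
- **likelihood** — per-phenotype likelihood ratios for disease contrasts,
  `LR+ = sens/(1−spec)` and `LR− = (1−sens)/spec`, top-k discriminator
  screens with minimum-observation and finiteness constraints, and external
  test handling including contrast inversion;
- **bayes** — a naive Bayesian diagnostic calculator combining age-based
  priors, phenotype LRs and external tests into per-disease post-test odds
  (`posterior odds = prior odds × Π LR`), a normalised multi-class
  posterior, screening projections, and the inverse query ("which
  observation would best resolve this differential?");
- **synth** — a synthetic literature-corpus simulator with known ground
  truth and per-study reporting censoring, plus parameter-recovery reports.

## Worked example

A small synthetic example corpus and query ship with the package:

```r
library(metaphen)

corpus <- read_corpus(system.file("extdata", "example_corpus_synthetic",
                                  package = "metaphen"))
profiles <- sapply(c("PD", "MSA", "PSP", "DLB"), build_profile,
                   corpus = corpus, simplify = FALSE)

top_discriminators(profiles, "MSA", "PD", k = 3)
#> # A tibble: 3 × 10
#>   term_id    disease_a disease_b sensitivity specificity lr_positive lr_negative
#> 1 HP:0001251 MSA       PD               0.55       0.95        11.0        0.474
#> 2 HP:0001278 MSA       PD               0.75       0.694        2.45       0.360
#> 3 HP:0033712 MSA       PD               0.5        0.606        1.27       0.825
```

Ataxia (HP:0001251) is the strongest discriminator of MSA from PD in this
corpus: it occurs in 55% of MSA cases but only 5% of PD cases, so observing
it multiplies the odds of MSA vs PD by 11.

A 50-year-old presenting with resting tremor, REM sleep behaviour disorder
and orthostatic hypotension:

```r
query <- read_query(system.file("extdata", "example_query.json",
                                package = "metaphen"))
result <- posterior(query, profiles)
result
#> <diagnostic_result> mode = one_vs_rest
#>   PD    pre 0.50  total LR    1.734  odds    1.768  prob 0.64  posterior 0.49
#>   MSA   pre 0.37  total LR    1.879  odds    1.091  prob 0.52  posterior 0.44
#>   DLB   pre 0.05  total LR    1.565  odds    0.091  prob 0.08  posterior 0.07
#>   PSP   pre 0.07  total LR    0.015  odds    0.001  prob 0.00  posterior 0.00
```

The pre-test column is the age-conditional prior from the pooled onset
Gaussians; each finding then multiplies the disease-vs-rest odds by its
likelihood ratio. PD and MSA remain in contention (this combination of
findings is common to both), while PSP is all but excluded — RBD and
tremor are rare in PSP. `tidy(result)` returns the table, `glance(result)`
the modal diagnosis, and `autoplot(result)` a probability chart.
`sequential_update()` folds in new evidence (a biomarker result, a new
sign) without rebuilding the query.

Screening arithmetic, e.g. a seed-amplification assay (sensitivity 0.98,
specificity 0.953) applied to 10,000 people at 10% prevalence:

```r
screening_projection(10000, 0.10, 0.98, 0.953)
#>       n prevalence sensitivity specificity    TP    FP    FN    TN   ppv   npv
#> 1 10000        0.1        0.98       0.953   980  423.  20.0  8577 0.699 0.998
```

980 of the 1000 true cases are detected, but 423 of the 9000 unaffected
screen positive, so ~30% of positives are false — the positive predictive
value is only 0.70 despite the excellent test.

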