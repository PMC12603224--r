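---
title: "Methods: metaphenomic annotation and probabilistic diagnosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metaphenomic annotation and probabilistic diagnosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaphen)
```

## The data model

Clinicopathological publications report cohorts, not individual cases. A
*metaphenomic annotation* therefore stores cohort-level evidence: the
post-mortem (pathological) diagnosis and number of cases, optional summary
statistics for age of onset, age at death and disease duration, an optional
cross-tab of final in-life diagnoses, and phenotype observations as
`(term_id, n_present, n_assessed)` counts against a phenotype ontology.

Two conventions are load-bearing throughout the package:

- **Missing is not zero.** A publication that does not mention a sign tells
  us nothing about its frequency. Unreported fields are absent (`NULL`/`NA`),
  and a cohort that did not assess a term contributes neither to its
  numerator nor to its denominator. This propagates all the way to the
  diagnostic calculator, where only findings explicitly asserted present or
  absent contribute evidence.
- **Counts, not per-study frequencies.** Frequencies are always computed
  from counts summed across cohorts, so sample-size weighting falls out of
  the arithmetic rather than being imposed afterwards.

## Pooling and Gaussian models

Per-cohort summaries `(mean_i, sd_i, n_i)` are pooled as the statistics of
the concatenated raw samples:

$$\bar x = \frac{\sum_i n_i \bar x_i}{\sum_i n_i}, \qquad
s^2 = \frac{\sum_i (n_i - 1) s_i^2 + \sum_i n_i (\bar x_i - \bar x)^2}
           {\sum_i n_i - 1}.$$

With sample standard deviations in (the `n−1` convention publications use),
this is exactly the mean and SD one would obtain from the concatenated raw
values, which is how the implementation is tested (to 1e-9 against a
concatenation oracle). It is invariant to cohort order and to splitting any
cohort in two.

Onset and survival are modelled as plain normal densities with the pooled
mean and SD, evaluated on fixed supports: 30–100 years for age of onset,
0–30 years for disease duration. The density is *not* renormalised after
truncation — the supports are evaluation windows, not a truncated-normal
model — and the survival function is `1 − Φ((t − μ)/σ)`, so the 50%
survival point sits at the pooled mean. These choices mirror standard
practice of fitting a `normpdf` over a clinically plausible range; they are
deliberately simple (no Kaplan–Meier, no censoring model) because the
literature reports summaries, not survival curves.

Age-conditional pre-test probabilities normalise weighted onset densities:
$P(d \mid \text{age}) \propto w_d f_d(\text{age})$. The default weights are
each disease's share of pooled case counts; a uniform-weight flag is
provided because the choice is genuinely open — case-count weighting treats
the literature's sampling as representative of clinical incidence, which is
at best approximate. The normalisation is over the user's differential; an
`OTHER` class can be included simply by passing a profile for it.

## Group comparisons

Differences in onset/death/duration across diseases use a Kruskal–Wallis
omnibus test (with tie correction, via `stats::kruskal.test`); pairwise
Wilcoxon rank-sum tests run only when the omnibus is significant, with a
fixed pairwise threshold of 0.005 (a Bonferroni-style constant rather than a
per-family adjustment, matching how such thresholds are usually reported).
Pairwise tests use the exact rank-sum distribution when both groups have at
most 25 values and no ties, and the normal approximation with continuity and
tie correction otherwise. The exact branch is validated against the
closed-form permutation count (e.g. two disjoint groups of three have
two-sided p = 2/C(6,3) = 0.1).

## Confusion analysis

The K×K confusion matrix cross-tabulates final in-life diagnoses (rows, the
prediction) against pathological diagnoses (columns, the truth). `OTHER`
sublabels (`OTHER:AD`, `OTHER:FTD`, ...) collapse to a single `OTHER` class
for analysis but are preserved in the data. The in-life label CBS
(corticobasal syndrome) is, by default, counted as clinical CBD, since CBD
pathology presents as CBS in life; the equivalence is a flag because some
analyses want the syndromic label kept distinct.

Each disease collapses to a 2×2 table one-vs-rest: sensitivity
`TP/(TP+FN)`, specificity `TN/(TN+FP)`, balanced accuracy their mean.
Row- and column-normalised rate matrices give the misdiagnosis and
missed-diagnosis views; a zero margin yields `NA`, never 0 (missing is not
zero, again). Balanced accuracy over publication-year windows
(`accuracy_timeline()`) exposes drift in diagnostic accuracy; windows with
no pathological cases of the target disease are omitted rather than
reported as 0.

## Likelihood ratios over the ontology

A phenotype is treated as a diagnostic test for disease *a* against disease
*b*: sensitivity is its pooled frequency in *a*, specificity one minus its
pooled frequency in *b*, and

$$LR^+ = \frac{\text{sens}}{1-\text{spec}}, \qquad
LR^- = \frac{1-\text{sens}}{\text{spec}}.$$

Two constraints guard against literature artefacts:

- **`min_assessed`** (default 10 per side): thinly assessed terms produce
  unstable frequencies; the floor's exact value is a package default chosen
  as the smallest cohort size at which a frequency estimate is meaningfully
  better than anecdote.
- **`zero_policy`**: a term never reported in the comparator has an
  unbounded LR⁺. Because absent reporting cannot be assumed to mean an
  absent sign, such candidate pathognomonic terms are excluded by default
  (`finite = FALSE`, `lr_positive = NA`). A Haldane-style correction
  (+0.5/+1 on both frequencies) is available for exploration and converges
  to the uncorrected ratio as counts grow.

Counts can optionally be propagated up the is-a hierarchy before the
screen. Cohort counts cannot be union-propagated (per-case overlap between
sibling terms is unknown), so the default mode takes the **maximum**
`n_present` among a term's descendants — a conservative lower bound that
never double-counts — with a capped-sum upper bound as the alternative.
Whether the published LR screens propagated counts or used terms as
annotated is not knowable from summaries alone, so propagation is a flag,
off by default.

`top_discriminators()` ranks shared terms by LR⁺ descending (ties broken by
larger total assessed count, then term id, so rankings are deterministic);
an `|log LR|` metric is available when strong negative predictors should
rank equally.

## The diagnostic calculator

The calculator is a naive Bayesian classifier over a user-chosen
differential. Evidence enters as likelihood ratios: present findings
contribute LR⁺, explicitly-absent findings LR⁻, and external tests
contribute ratios from their published sensitivity/specificity. A test
validated against one contrast (e.g. a biomarker validated for atypical
Parkinsonism) is *inverted* — both values replaced by their complements —
when applied to a disease outside that contrast.

Combining evidence across more than two diseases admits several
conventions, and the choice was genuinely open. The package computes three
views and is explicit about the differences:

1. **One-vs-rest odds (canonical).** For each disease,
   `post odds = prior odds × Π (finding's d-vs-REST ratio)`, with the rest
   frequency a case-count-weighted average over the other diseases. With
   two diseases this is exact Bayes.
2. **Pairwise report.** Per-contrast LR products for every opponent, in the
   style of a published worked-example table, with the disease's odds
   multiplying all its contrast products. This view is a report format; its
   products are not claimed to be calibrated probabilities.
3. **Normalised posterior.** Computed as exact naive Bayes:
   `posterior(d) ∝ prior(d) × Π P(evidence | d)`, normalised to sum to 1.
   This is *not* the normalisation of view 1: the product of per-finding
   one-vs-rest ratios has a disease-dependent denominator that does not
   cancel, so normalising LR products does not recover Bayes for three or
   more diseases. On synthetic worlds with conditionally independent
   findings the normalised posterior equals enumeration Bayes to 1e-9,
   which is the property the test suite enforces.

The per-disease probabilities `odds/(1+odds)` from views 1–2 intentionally
need not sum to 1 across the differential — each is a calibrated answer to
"this disease versus the rest", not a share of a partition.

Degenerate evidence is handled explicitly: a disease whose profile never
assessed a queried term (or below `min_assessed`) is dropped from the
differential and reported, not silently zeroed; a zero frequency for a
present finding legitimately zeroes that disease; an unbounded ratio
(comparator frequency zero) is excluded with a flag by default, or capped
at 10³ (10⁻³ reciprocal) under an explicit pathognomonic opt-in.
`sequential_update()` recomputes on the enlarged query, so updating is
associative by construction.

Naive Bayes assumes conditional independence of findings. That cannot be
verified from cohort summaries; the practical mitigation is to choose
findings from different phenotype domains and to use hierarchy aggregation
to collapse obviously collinear terms (all tremor subtypes into "tremor")
rather than stacking them.

## The synthetic corpus generator

`simulate_corpus()` generates literature-like corpora with known truth so
every analysis stage is testable without external data. Each study draws a
disease (case-count weights), a log-uniform size, per-case onsets and
durations from the disease's Gaussians — negative durations are resampled,
and age at death is onset + duration per case, so the three summaries are
mutually consistent — binomial phenotype counts, and multinomial in-life
labels from the confusion row of the true diagnosis. Reporting censoring is
applied per study and per term, independent of the drawn values: by default
each study reports sex with probability 0.467, a misdiagnosis cross-tab
with probability 0.62, each phenotype with probability 0.6, and references
timings to diagnosis rather than symptom onset with probability 0.15. The
default scale is 125 studies of 10–200 cases. Defaults for the Gaussians,
weights and censoring probabilities mirror the published corpus's printed
summaries; the confusion matrix and phenotype frequencies are plausible
values informed by reported misdiagnosis proportions and clinical
knowledge. They describe the *shape* of the literature, not ground truth
for any real corpus.

What the generator deliberately does not emulate: temporal ordering of
symptom emergence, dual-pathology staging, duplicated cases across
overlapping cohorts, reporting bias that depends on the observed frequency
(censoring is independent of the draw, which is exactly why censoring does
not bias frequency estimates in the test suite — real publication bias
need not be so kind), and drift of diagnostic criteria over time. Passing
recovery tests therefore demonstrates that the estimators are consistent
under honest-but-patchy reporting, not that the real literature is free of
systematic bias.

Because negative durations are resampled, the realised generating mean of a
duration is the zero-truncated normal mean; `recovery_report()` compares
against that, with 3-standard-error intervals for means and exact binomial
99% intervals for proportions.

## Numerical choices and problem sizes

- Per-study random substreams are derived from the corpus seed and the
  study index, so a study's draws do not depend on iteration order.
- Exact Wilcoxon below 25 per group and no ties; normal approximation with
  corrections otherwise.
- Probabilities are reported to 2 decimal places in CLI/CSV output and at
  full precision in JSON.
- The test suite runs its property checks at deliberately modest sizes —
  random DAGs of 50 nodes, corpora of 10–120 studies, 100-seed coverage
  loops, a single 10⁶-draw Monte-Carlo check — chosen so the whole suite
  completes in about a minute while keeping Monte-Carlo noise far below the
  tolerances asserted.

## Known limitations

- No confidence intervals on likelihood ratios in user output (the test
  suite uses delta-method intervals internally); no multiple-testing
  control in the LR screen.
- The Gaussian survival model ignores censoring and skew; it is a summary
  device, not a survival analysis.
- Cohort-level counts fundamentally cannot recover per-case co-occurrence,
  so hierarchy aggregation is bounded (max / capped-sum), not exact.
- Pooling mixes symptom-onset- and diagnosis-referenced timings without
  correction; the `onset_reference` flag is preserved per cohort so a
  sensitivity analysis can split them.
- No de-duplication of cases appearing in multiple publications.
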