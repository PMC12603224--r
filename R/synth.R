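#' Default simulation configuration
#'
#' Ground-truth parameters for the synthetic literature-corpus simulator.
#' Defaults mirror the published clinicopathological corpus this package's
#' format targets: five diseases with Gaussian onset and duration
#' distributions matching the printed pooled means/SDs, case-count weights
#' matching the published per-diagnosis totals, a misdiagnosis confusion
#' matrix consistent with the reported misdiagnosis proportions, 125 studies
#' with log-uniform sizes of 10-200 cases, and per-study reporting censoring
#' (each study reports sex with probability 0.467, misdiagnosis data with
#' probability 0.62, each phenotype term with probability 0.6, and measures
#' timings from diagnosis rather than symptom onset with probability 0.15).
#' These defaults describe the shape of the literature, not ground truth for
#' any real corpus.
#'
#' @param diseases Optional subset of diseases to simulate.
#' @param n_studies Number of studies in the corpus.
#' @param study_size_range Log-uniform bounds on per-study case counts.
#' @param phenotype_report_prob Per-study probability that each configured
#'   term is assessed and reported.
#' @param sex_report_prob Per-study probability of reporting sex counts.
#' @param misdiagnosis_report_prob Per-study probability of reporting the
#'   clinical-vs-pathological cross-tab.
#' @param diagnosis_onset_prob Per-study probability that timings are
#'   referenced to diagnosis instead of symptom onset.
#' @return A `sim_config` list with elements `diseases` (per-disease tibble:
#'   `disease`, `onset_mean`, `onset_sd`, `duration_mean`, `duration_sd`,
#'   `weight`), `phenotype_freq` (tibble `disease`, `term_id`, `freq`),
#'   `confusion` (row-stochastic matrix P(clinical | pathological)) and the
#'   corpus-level fields above.
#' @export
sim_config <- function(diseases = NULL,
                       n_studies = 125L,
                       study_size_range = c(10, 200),
                       phenotype_report_prob = 0.6,
                       sex_report_prob = 0.467,
                       misdiagnosis_report_prob = 0.62,
                       diagnosis_onset_prob = 0.15) {
  disease_tab <- tibble(
    disease = c("PD", "MSA", "PSP", "DLB", "CBD"),
    onset_mean = c(62.75, 59.19, 65.60, 69.34, 62.64),
    onset_sd = c(11.11, 9.12, 8.10, 10.46, 7.78),
    duration_mean = c(14.64, 7.19, 7.39, 7.85, 6.91),
    duration_sd = c(6.96, 2.60, 3.80, 5.75, 3.26),
    weight = c(2406, 1594, 1835, 834, 354)
  )
  freq_tab <- default_phenotype_freqs()
  confusion <- default_confusion_probs()
  if (!is.null(diseases)) {
    disease_tab <- filter(disease_tab, .data$disease %in% diseases)
    freq_tab <- filter(freq_tab, .data$disease %in% diseases)
    confusion <- confusion[diseases, , drop = FALSE]
  }
  cfg <- structure(
    list(diseases = disease_tab, phenotype_freq = freq_tab,
         confusion = confusion, n_studies = as.integer(n_studies),
         study_size_range = study_size_range,
         phenotype_report_prob = phenotype_report_prob,
         sex_report_prob = sex_report_prob,
         misdiagnosis_report_prob = misdiagnosis_report_prob,
         diagnosis_onset_prob = diagnosis_onset_prob),
    class = "sim_config"
  )
  validate_sim_config(cfg)
  cfg
}

default_phenotype_freqs <- function() {
  tribble_freqs <- list(
    # term                    PD    MSA   PSP   DLB   CBD
    "HP:0002322" = c(0.75, 0.30, 0.12, 0.45, 0.14),  # resting tremor
    "HP:0002067" = c(0.95, 0.85, 0.90, 0.80, 0.75),  # bradykinesia
    "HP:0001251" = c(0.05, 0.55, 0.10, 0.08, 0.12),  # ataxia
    "HP:0010307" = c(0.01, 0.30, 0.02, 0.01, 0.01),  # stridor
    "HP:0000605" = c(0.03, 0.08, 0.70, 0.05, 0.20),  # supranuclear gaze palsy
    "HP:0002527" = c(0.35, 0.45, 0.80, 0.40, 0.45),  # falls
    "HP:0001278" = c(0.30, 0.75, 0.15, 0.45, 0.10),  # orthostatic hypotension
    "HP:0033712" = c(0.40, 0.50, 0.10, 0.55, 0.05),  # RBD
    "HP:0100543" = c(0.30, 0.20, 0.45, 0.90, 0.50),  # cognitive impairment
    "HP:0000738" = c(0.25, 0.08, 0.10, 0.65, 0.10),  # hallucinations
    "HP:0041008" = c(0.00, 0.00, 0.05, 0.00, 0.35),  # cortical sensory loss
    "HP:0100639" = c(0.25, 0.60, 0.10, 0.20, 0.05)   # erectile dysfunction
  )
  bind_rows(imap(tribble_freqs, function(f, term) {
    tibble(disease = c("PD", "MSA", "PSP", "DLB", "CBD"), term_id = term,
           freq = f)
  }))
}

default_confusion_probs <- function() {
  labels <- c("PD", "MSA", "PSP", "DLB", "CBD", "OTHER")
  m <- rbind(
    PD  = c(0.860, 0.054, 0.016, 0.000, 0.000, 0.070),
    MSA = c(0.083, 0.830, 0.069, 0.000, 0.000, 0.018),
    PSP = c(0.085, 0.056, 0.800, 0.000, 0.036, 0.023),
    DLB = c(0.020, 0.080, 0.000, 0.780, 0.000, 0.120),
    CBD = c(0.050, 0.045, 0.174, 0.000, 0.600, 0.131)
  )
  colnames(m) <- labels
  sweep(m, 1, rowSums(m), "/")
}

validate_sim_config <- function(cfg) {
  d <- cfg$diseases
  if (nrow(d) == 0L) abort("sim_config has no diseases")
  if (any(d$onset_sd <= 0) || any(d$duration_sd <= 0)) {
    abort("onset/duration sd must be positive")
  }
  if (any(d$weight < 0) || sum(d$weight) == 0) abort("invalid disease weights")
  probs <- c(cfg$phenotype_report_prob, cfg$sex_report_prob,
             cfg$misdiagnosis_report_prob, cfg$diagnosis_onset_prob,
             cfg$phenotype_freq$freq)
  if (any(probs < 0 | probs > 1)) abort("probabilities must lie in [0, 1]")
  if (any(cfg$study_size_range < 1) ||
      cfg$study_size_range[1] > cfg$study_size_range[2]) {
    abort("study_size_range must be ordered and >= 1")
  }
  if (any(abs(rowSums(cfg$confusion) - 1) > 1e-9)) {
    abort("confusion rows must sum to 1")
  }
  if (!all(d$disease %in% rownames(cfg$confusion))) {
    abort("confusion matrix must cover every simulated disease")
  }
  invisible(cfg)
}

#' Simulate a synthetic literature corpus
#'
#' Generates a corpus of cohort annotations with known ground truth. Each
#' study draws a pathological diagnosis (case-count weights), a log-uniform
#' size, per-case ages of onset and durations from the disease's Gaussians
#' (negative durations resampled; age at death = onset + duration per case,
#' so the three summaries are mutually consistent), per-term phenotype counts
#' as Binomial(n, freq), and — when the study reports misdiagnosis data —
#' in-life labels drawn from the confusion row of its true diagnosis.
#' Reporting censoring is applied per study and per term, independent of the
#' drawn values, emulating the patchy reporting of the published literature.
#'
#' Per-study random substreams are derived from `seed` and the study index,
#' so each study's draws do not depend on iteration order.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; the corpus is a deterministic function of
#'   `(config, seed)`.
#' @return A list with `corpus` (a corpus tibble) and `truth` (a
#'   `synthetic_truth`: the config, the seed, and a per-study tibble of
#'   realised latent diagnoses and sizes).
#' @export
simulate_corpus <- function(config = sim_config(), seed = 1L) {
  validate_sim_config(config)
  d <- config$diseases
  set.seed(seed %% .Machine$integer.max)
  study_seeds <- sample.int(.Machine$integer.max - 1L, config$n_studies)
  rows <- vector("list", config$n_studies)
  latent <- vector("list", config$n_studies)
  for (i in seq_len(config$n_studies)) {
    set.seed(study_seeds[i])
    di <- sample.int(nrow(d), 1L, prob = d$weight / sum(d$weight))
    disease <- d$disease[di]
    lo <- log(config$study_size_range[1]); hi <- log(config$study_size_range[2])
    n <- max(1L, as.integer(round(exp(runif(1, lo, hi)))))

    onset <- rnorm(n, d$onset_mean[di], d$onset_sd[di])
    duration <- rnorm(n, d$duration_mean[di], d$duration_sd[di])
    while (any(duration <= 0)) {
      bad <- duration <= 0
      duration[bad] <- rnorm(sum(bad), d$duration_mean[di], d$duration_sd[di])
    }
    death <- onset + duration

    freqs <- filter(config$phenotype_freq, .data$disease == !!disease)
    reported <- runif(nrow(freqs)) < config$phenotype_report_prob
    ph <- if (any(reported)) {
      tibble(
        term_id = freqs$term_id[reported],
        n_present = rbinom(sum(reported), n, freqs$freq[reported]),
        n_assessed = rep(n, sum(reported))
      )
    } else {
      empty_phenotypes()
    }

    cd <- NULL
    if (runif(1) < config$misdiagnosis_report_prob) {
      draw <- rmultinom(1, n, config$confusion[disease, ])[, 1]
      cd <- tibble(label = names(draw), count = as.integer(draw))
      cd <- filter(cd, .data$count > 0L)
    }

    n_female <- n_male <- NA_integer_
    if (runif(1) < config$sex_report_prob) {
      n_female <- rbinom(1, n, 0.45)
      n_male <- n - n_female
    }
    onset_ref <- if (runif(1) < config$diagnosis_onset_prob) "diagnosis" else {
      "symptom_onset"
    }

    rows[[i]] <- cohort_annotation(
      source_id = sprintf("SYN:%04d", i),
      publication_year = 1992L + (i %% 31L),
      cohort_label = "cohort-1",
      path_diagnosis = disease,
      n_cases = n,
      n_female = n_female, n_male = n_male,
      onset = age_summary(values = onset),
      death = age_summary(values = death),
      duration = age_summary(values = duration),
      onset_reference = onset_ref,
      clinical_diagnoses = cd,
      phenotypes = ph
    )
    latent[[i]] <- tibble(study = i, disease = disease, n = n,
                          reported_misdiagnosis = !is.null(cd))
  }
  corpus <- as_corpus(arrange(bind_rows(rows), .data$source_id,
                              .data$cohort_label))
  truth <- structure(
    list(config = config, seed = seed, studies = bind_rows(latent)),
    class = "synthetic_truth"
  )
  list(corpus = corpus, truth = truth)
}

#' Parameter-recovery report for a synthetic corpus
#'
#' Compares estimates computed from a simulated corpus against the generating
#' parameters, one row per parameter. Means use a 3-standard-error interval
#' around the truth; proportions (phenotype frequencies and confusion rows)
#' use the exact binomial 99% confidence interval of the estimate and check
#' that it covers the truth. Duration truths are the zero-truncated normal
#' means, since the generator resamples negative durations.
#'
#' @param corpus The simulated corpus.
#' @param truth The matching `synthetic_truth`.
#' @return A tibble: `parameter`, `disease`, `truth`, `estimate`, `error`,
#'   `within_ci`.
#' @export
recovery_report <- function(corpus, truth) {
  cfg <- truth$config
  out <- list()
  for (i in seq_len(nrow(cfg$diseases))) {
    d <- cfg$diseases$disease[i]
    if (!any(collapse_other(corpus$path_diagnosis) == d)) next
    prof <- build_profile(corpus, d)

    for (fld in c("onset", "duration")) {
      true_mu <- cfg$diseases[[paste0(fld, "_mean")]][i]
      true_sd <- cfg$diseases[[paste0(fld, "_sd")]][i]
      if (fld == "duration") {
        # negative durations are resampled, so the realised generating mean
        # is the zero-truncated normal mean
        a <- -true_mu / true_sd
        true_mu <- true_mu + true_sd * dnorm(a) / (1 - pnorm(a))
      }
      p <- prof[[fld]]
      if (is.null(p)) next
      se <- true_sd / sqrt(p$pooled$n_total)
      out[[length(out) + 1L]] <- tibble(
        parameter = paste0(fld, "_mean"), disease = d, truth = true_mu,
        estimate = p$pooled$mean, error = p$pooled$mean - true_mu,
        within_ci = abs(p$pooled$mean - true_mu) <= 3 * se
      )
    }

    freqs <- filter(cfg$phenotype_freq, .data$disease == !!d)
    tab <- prof$phenotype_table
    for (j in seq_len(nrow(freqs))) {
      k <- match(freqs$term_id[j], tab$term_id)
      if (is.na(k)) next
      ci <- binom.test(tab$n_present[k], tab$n_assessed[k],
                       conf.level = 0.99)$conf.int
      est <- tab$n_present[k] / tab$n_assessed[k]
      out[[length(out) + 1L]] <- tibble(
        parameter = paste0("freq_", freqs$term_id[j]), disease = d,
        truth = freqs$freq[j], estimate = est, error = est - freqs$freq[j],
        within_ci = freqs$freq[j] >= ci[1] & freqs$freq[j] <= ci[2]
      )
    }
  }

  # confusion rows: P(clinical | pathological) against the generating matrix
  has_xtab <- map_lgl(corpus$clinical_diagnoses, ~ !is.null(.x) && nrow(.x) > 0L)
  if (any(has_xtab)) {
    cm <- build_confusion(corpus[has_xtab, ], labels = colnames(cfg$confusion),
                          cbs_equals_cbd = TRUE)
    for (d in rownames(cfg$confusion)) {
      col_total <- sum(cm$counts[, d])
      if (col_total == 0L) next
      for (cl in colnames(cfg$confusion)) {
        x <- cm$counts[cl, d]
        ci <- binom.test(x, col_total, conf.level = 0.99)$conf.int
        truth_p <- cfg$confusion[d, cl]
        out[[length(out) + 1L]] <- tibble(
          parameter = paste0("confusion_", cl, "_given_", d), disease = d,
          truth = truth_p, estimate = x / col_total,
          error = x / col_total - truth_p,
          within_ci = truth_p >= ci[1] & truth_p <= ci[2]
        )
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble(parameter = character(), disease = character(),
                  truth = numeric(), estimate = numeric(), error = numeric(),
                  within_ci = logical()))
  }
  bind_rows(out)
}
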