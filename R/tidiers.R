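#' Tidy a disease profile
#'
#' One row per phenotype term with pooled counts and frequency.
#'
#' @param x A `disease_profile`.
#' @param ... Unused.
#' @return A tibble: `disease`, `term_id`, `n_present`, `n_assessed`,
#'   `frequency`, `propagated`.
#' @method tidy disease_profile
#' @export
tidy.disease_profile <- function(x, ...) {
  mutate(x$phenotype_table, disease = x$disease,
         frequency = .data$n_present / .data$n_assessed,
         .before = "term_id")
}

#' @rdname tidy.disease_profile
#' @return `glance()`: a one-row tibble with pooled onset/death/duration
#'   summaries and corpus bookkeeping.
#' @method glance disease_profile
#' @export
glance.disease_profile <- function(x, ...) {
  g <- function(f, what) {
    if (is.null(x[[f]])) NA_real_ else x[[f]]$pooled[[what]]
  }
  tibble(
    disease = x$disease, n_sources = x$n_sources, n_cases = x$n_cases,
    n_terms = nrow(x$phenotype_table),
    onset_mean = g("onset", "mean"), onset_sd = g("onset", "sd"),
    death_mean = g("death", "mean"), death_sd = g("death", "sd"),
    duration_mean = g("duration", "mean"), duration_sd = g("duration", "sd")
  )
}

#' Tidy a confusion matrix
#'
#' @param x A `confusion_matrix`.
#' @param ... Unused.
#' @return A long tibble: `clinical`, `pathological`, `count`.
#' @method tidy confusion_matrix
#' @export
tidy.confusion_matrix <- function(x, ...) {
  as_tibble(as.data.frame.table(x$counts, responseName = "count",
                                stringsAsFactors = FALSE))
}

#' @rdname tidy.confusion_matrix
#' @return `glance()`: per-disease one-vs-rest performance (one row per
#'   disease with pathological cases).
#' @method glance confusion_matrix
#' @export
glance.confusion_matrix <- function(x, ...) {
  with_cases <- x$labels[colSums(x$counts) > 0]
  bind_rows(map(with_cases, binary_performance, cm = x))
}

#' Tidy a diagnostic result
#'
#' @param x A `diagnostic_result`.
#' @param ... Unused.
#' @return The per-disease tibble (`pre_test_probability`, `total_lr`,
#'   `post_test_odds`, `probability`, `posterior`).
#' @method tidy diagnostic_result
#' @export
tidy.diagnostic_result <- function(x, ...) {
  x$diseases
}

#' @rdname tidy.diagnostic_result
#' @return `glance()`: a one-row tibble with the modal diagnosis, its
#'   normalised posterior, and evidence bookkeeping.
#' @method glance diagnostic_result
#' @export
glance.diagnostic_result <- function(x, ...) {
  top <- x$diseases[which.max(x$diseases$posterior), ]
  tibble(
    most_likely = top$disease, posterior = top$posterior,
    probability = top$probability, mode = x$mode,
    n_findings = nrow(x$query$findings),
    n_tests = if (is.null(x$query$external_tests)) 0L else {
      nrow(x$query$external_tests)
    },
    n_dropped = length(unique(x$dropped$disease)),
    n_excluded_evidence = nrow(x$excluded_evidence)
  )
}

#' Tidy group-comparison tests
#' @param x A `group_tests` object.
#' @param ... Unused.
#' @return The pairwise tibble (`group_a`, `group_b`, `p_value`,
#'   `significant`).
#' @method tidy group_tests
#' @export
tidy.group_tests <- function(x, ...) x$pairwise

#' @rdname tidy.group_tests
#' @method glance group_tests
#' @export
glance.group_tests <- function(x, ...) x$omnibus
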