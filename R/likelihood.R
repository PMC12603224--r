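#' Likelihood-ratio configuration
#'
#' @param min_assessed Minimum number of assessed cases required on each side
#'   of a contrast before a term's likelihood ratio is computed (default 10);
#'   published reporting of rare features is patchy, so thinly assessed terms
#'   are unreliable.
#' @param zero_policy How to treat zero counts: `"exclude"` (default) flags
#'   the ratio non-finite when the comparator frequency is 0 — absent
#'   reporting cannot be assumed to mean an absent sign — while `"haldane"`
#'   adds 0.5 to numerators and 1 to denominators of both frequencies so
#'   candidate pathognomonic signs can be explored with finite ratios.
#' @param propagate Whether profile counts were propagated up the ontology
#'   (affects which terms are available, not the arithmetic).
#' @return An `lr_config` list.
#' @export
lr_config <- function(min_assessed = 10L, zero_policy = c("exclude", "haldane"),
                      propagate = FALSE) {
  if (min_assessed < 1L) abort("min_assessed must be >= 1")
  structure(list(min_assessed = as.integer(min_assessed),
                 zero_policy = match.arg(zero_policy),
                 propagate = propagate),
            class = "lr_config")
}

profile_counts <- function(profile, term_id) {
  tab <- profile$phenotype_table
  i <- match(term_id, tab$term_id)
  if (is.na(i)) return(NULL)
  list(n_present = tab$n_present[i], n_assessed = tab$n_assessed[i])
}

#' Likelihood ratio of a phenotype for one disease contrast
#'
#' Treats the phenotype as a diagnostic test for `disease_a` against
#' `disease_b`: sensitivity is the pooled frequency of the term in a,
#' specificity is one minus its pooled frequency in b, and
#' `LR+ = sensitivity / (1 - specificity)`,
#' `LR- = (1 - sensitivity) / specificity`. Frequencies are pooled counts
#' summed across cohorts (sample-size weighting falls out naturally), not
#' averaged per-study frequencies.
#'
#' When the term is never reported in b, `LR+` is unbounded: under
#' `zero_policy = "exclude"` the row is flagged `finite = FALSE` with
#' `lr_positive = NA`; under `"haldane"` both frequencies get a 0.5/1
#' continuity correction.
#'
#' @param profile_a,profile_b `disease_profile`s for the two sides.
#' @param term_id Phenotype term CURIE.
#' @param config An [lr_config()].
#' @return A one-row tibble: `term_id`, `disease_a`, `disease_b`,
#'   `sensitivity`, `specificity`, `lr_positive`, `lr_negative`,
#'   `n_a_assessed`, `n_b_assessed`, `finite`.
#' @export
contrast_lr <- function(profile_a, profile_b, term_id, config = lr_config()) {
  a <- profile_counts(profile_a, term_id)
  b <- profile_counts(profile_b, term_id)
  if (is.null(a) || a$n_assessed < config$min_assessed) {
    abort(paste0("insufficient observations of ", term_id, " in ",
                 profile_a$disease, " (need >= ", config$min_assessed, ")"))
  }
  if (is.null(b) || b$n_assessed < config$min_assessed) {
    abort(paste0("insufficient observations of ", term_id, " in ",
                 profile_b$disease, " (need >= ", config$min_assessed, ")"))
  }
  lr_row(term_id, profile_a$disease, profile_b$disease,
         a$n_present, a$n_assessed, b$n_present, b$n_assessed, config)
}

lr_row <- function(term_id, disease_a, disease_b, pres_a, n_a, pres_b, n_b,
                   config) {
  if (config$zero_policy == "haldane") {
    freq_a <- (pres_a + 0.5) / (n_a + 1)
    freq_b <- (pres_b + 0.5) / (n_b + 1)
  } else {
    freq_a <- pres_a / n_a
    freq_b <- pres_b / n_b
  }
  sens <- freq_a
  spec <- 1 - freq_b
  finite <- freq_b > 0
  tibble(
    term_id = term_id, disease_a = disease_a, disease_b = disease_b,
    sensitivity = sens, specificity = spec,
    lr_positive = if (finite) sens / (1 - spec) else NA_real_,
    lr_negative = if (spec > 0) (1 - sens) / spec else NA_real_,
    n_a_assessed = n_a, n_b_assessed = n_b,
    finite = finite
  )
}

#' One-vs-rest likelihood ratio
#'
#' Contrasts one disease against the weighted pool of the remaining diseases:
#' the rest-side frequency is the weighted average of the other diseases'
#' pooled frequencies, with `rest_weights` renormalised over the diseases that
#' actually assessed the term. With two diseases this reduces to
#' [contrast_lr()].
#'
#' @param profiles Named list of `disease_profile`s.
#' @param disease The focal disease (a name of `profiles`).
#' @param term_id Phenotype term CURIE.
#' @param rest_weights Optional named weights for the rest pool (defaults to
#'   each profile's case count).
#' @param config An [lr_config()].
#' @return A one-row tibble as [contrast_lr()], with `disease_b = "REST"`.
#' @export
one_vs_rest_lr <- function(profiles, disease, term_id, rest_weights = NULL,
                           config = lr_config()) {
  if (!disease %in% names(profiles)) abort(paste0("no profile for ", disease))
  a <- profile_counts(profiles[[disease]], term_id)
  if (is.null(a) || a$n_assessed < config$min_assessed) {
    abort(paste0("insufficient observations of ", term_id, " in ", disease))
  }
  rest <- profiles[setdiff(names(profiles), disease)]
  if (is.null(rest_weights)) {
    rest_weights <- setNames(map_dbl(rest, "n_cases"), names(rest))
  }
  counts <- map(rest, profile_counts, term_id = term_id)
  ok <- map_lgl(counts, ~ !is.null(.x) && .x$n_assessed >= config$min_assessed)
  if (!any(ok)) abort(paste0("no rest disease assesses ", term_id))
  w <- rest_weights[names(rest)[ok]]
  w <- w / sum(w)
  freqs <- map_dbl(counts[ok], ~ .x$n_present / .x$n_assessed)
  rest_freq <- sum(w * freqs)
  n_rest <- sum(map_dbl(counts[ok], "n_assessed"))
  # rest pseudo-counts carry the weighted frequency through lr_row's
  # arithmetic (haldane, when configured, corrects these pooled counts)
  lr_row(term_id, disease, "REST", a$n_present, a$n_assessed,
         rest_freq * n_rest, n_rest, config)
}

#' Top discriminating phenotype terms for a disease pair
#'
#' Screens every term assessed in both profiles and returns the `k` terms
#' with the largest finite positive likelihood ratios for `disease_a` against
#' `disease_b`. Terms failing the `min_assessed` floor on either side are
#' skipped; ties are broken by larger total assessed count, then by term id,
#' so the ranking is deterministic.
#'
#' @param profiles Named list of `disease_profile`s.
#' @param disease_a,disease_b The contrast.
#' @param k Maximum number of terms to return (default 5).
#' @param config An [lr_config()].
#' @param metric `"lr_positive"` (default, largest ratio first) or
#'   `"abs_log_lr"` (distance of the ratio from 1 on the log scale, treating
#'   strong negative predictors as equally informative).
#' @return A tibble of up to `k` rows as [contrast_lr()].
#' @export
top_discriminators <- function(profiles, disease_a, disease_b, k = 5L,
                               config = lr_config(),
                               metric = c("lr_positive", "abs_log_lr")) {
  metric <- match.arg(metric)
  pa <- profiles[[disease_a]]
  pb <- profiles[[disease_b]]
  if (is.null(pa) || is.null(pb)) abort("both profiles must be present")
  shared <- intersect(pa$phenotype_table$term_id, pb$phenotype_table$term_id)
  rows <- bind_rows(map(shared, function(t) {
    a <- profile_counts(pa, t)
    b <- profile_counts(pb, t)
    if (a$n_assessed < config$min_assessed ||
        b$n_assessed < config$min_assessed) return(NULL)
    lr_row(t, disease_a, disease_b, a$n_present, a$n_assessed,
           b$n_present, b$n_assessed, config)
  }))
  if (nrow(rows) == 0L) return(rows)
  rows <- filter(rows, .data$finite, !is.na(.data$lr_positive),
                 .data$lr_positive > 0)
  score <- if (metric == "lr_positive") rows$lr_positive else {
    abs(log10(rows$lr_positive))
  }
  ord <- order(-score, -(rows$n_a_assessed + rows$n_b_assessed), rows$term_id)
  head(rows[ord, , drop = FALSE], k)
}

#' Likelihood ratios of an external diagnostic test
#'
#' `lr_from_test()` converts a published sensitivity/specificity pair into
#' positive and negative likelihood ratios
#' (`LR+ = sens/(1-spec)`, `LR- = (1-sens)/spec`). `invert_test()` flips a
#' test validated against one contrast for use on the complementary contrast
#' by replacing both values with their complements — e.g. a blood
#' neurofilament light chain cut-off validated for atypical Parkinsonism
#' (sens 0.86, spec 0.85) becomes (0.14, 0.15) for the non-atypical group.
#'
#' @param sensitivity,specificity Proportions in `[0, 1]`.
#' @return `lr_from_test()`: a one-row tibble with `lr_positive`,
#'   `lr_negative`. `invert_test()`: a named numeric vector
#'   `c(sensitivity, specificity)`.
#' @export
lr_from_test <- function(sensitivity, specificity) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1)
  if (specificity == 1) {
    abort("specificity = 1 gives an unbounded LR+; use a finite bound")
  }
  if (specificity == 0) {
    abort("specificity = 0 gives an unbounded LR-; use a finite bound")
  }
  tibble(lr_positive = sensitivity / (1 - specificity),
         lr_negative = (1 - sensitivity) / specificity)
}

#' @rdname lr_from_test
#' @export
invert_test <- function(sensitivity, specificity) {
  stopifnot(sensitivity >= 0, sensitivity <= 1,
            specificity >= 0, specificity <= 1)
  c(sensitivity = 1 - sensitivity, specificity = 1 - specificity)
}

#' Full LR table for a disease pair
#'
#' Every shared term meeting the observation floor, with names from an
#' optional ontology; convenience wrapper used by the CLI `lr` subcommand.
#'
#' @param profiles Named list of `disease_profile`s.
#' @param disease_a,disease_b The contrast.
#' @param config An [lr_config()].
#' @param graph Optional `ontology_graph` for term names.
#' @param path Optional CSV output path.
#' @return A tibble with one row per eligible term (finite or not).
#' @export
lr_table <- function(profiles, disease_a, disease_b, config = lr_config(),
                     graph = NULL, path = NULL) {
  pa <- profiles[[disease_a]]
  pb <- profiles[[disease_b]]
  shared <- intersect(pa$phenotype_table$term_id, pb$phenotype_table$term_id)
  rows <- bind_rows(map(shared, function(t) {
    a <- profile_counts(pa, t)
    b <- profile_counts(pb, t)
    if (a$n_assessed < config$min_assessed ||
        b$n_assessed < config$min_assessed) return(NULL)
    lr_row(t, disease_a, disease_b, a$n_present, a$n_assessed,
           b$n_present, b$n_assessed, config)
  }))
  if (!is.null(graph) && nrow(rows) > 0L) {
    rows <- mutate(rows, term_name = graph$terms$name[
      match(.data$term_id, graph$terms$id)], .after = "term_id")
  }
  rows <- arrange(rows, desc(!is.na(.data$lr_positive)), desc(.data$lr_positive))
  if (!is.null(path)) write.csv(rows, path, row.names = FALSE)
  rows
}
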