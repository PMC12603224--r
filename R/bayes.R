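#' Probability/odds conversions
#'
#' The odds machinery of the diagnostic calculator: `o = p/(1-p)` and
#' `p = o/(1+o)`, mutual inverses. Probabilities of exactly 0 or 1 have no
#' finite odds and are rejected; cap likelihood ratios upstream instead.
#'
#' @param p Probability in (0, 1).
#' @param o Odds (>= 0).
#' @return The converted value(s).
#' @export
prob_to_odds <- function(p) {
  if (any(p <= 0 | p >= 1)) abort("probability must be strictly inside (0, 1)")
  p / (1 - p)
}

#' @rdname prob_to_odds
#' @export
odds_to_prob <- function(o) {
  if (any(o < 0)) abort("odds must be >= 0")
  o / (1 + o)
}

#' Build a diagnostic query
#'
#' A patient presentation for the calculator: an optional age, phenotype
#' findings asserted present or absent, and external diagnostic tests with
#' published sensitivity/specificity. Findings not mentioned contribute
#' nothing — absence must be asserted explicitly, because unreported is not
#' absent.
#'
#' @param age Optional age in years (drives the age-conditional prior).
#' @param findings Data frame with columns `term_id` and `status`
#'   (`"present"` or `"absent"`); each term at most once.
#' @param external_tests Optional data frame with columns `name`,
#'   `sensitivity`, `specificity`, `result` (`"positive"`/`"negative"`) and a
#'   list-column `applies_to` naming the diseases the published validation
#'   contrast covers; for other diseases the test is inverted
#'   (see [invert_test()]).
#' @param differential Ordered disease codes under consideration.
#' @param prior_override Optional named probabilities replacing the
#'   age-based prior (must cover the differential).
#' @return A `diagnostic_query` list.
#' @export
diagnostic_query <- function(age = NULL,
                             findings = NULL,
                             external_tests = NULL,
                             differential = c("PD", "MSA", "PSP", "DLB", "CBD"),
                             prior_override = NULL) {
  findings <- if (is.null(findings)) {
    tibble(term_id = character(), status = character())
  } else {
    as_tibble(findings)
  }
  if (anyDuplicated(findings$term_id)) {
    abort("each term_id may appear only once in findings")
  }
  if (!all(findings$status %in% c("present", "absent"))) {
    abort("finding status must be \"present\" or \"absent\"")
  }
  if (!is.null(external_tests)) {
    external_tests <- as_tibble(external_tests)
    stopifnot(all(c("name", "sensitivity", "specificity", "result",
                    "applies_to") %in% names(external_tests)))
    if (!all(external_tests$result %in% c("positive", "negative"))) {
      abort("test result must be \"positive\" or \"negative\"")
    }
  }
  if (!is.null(prior_override)) {
    if (!all(differential %in% names(prior_override))) {
      abort("prior_override must cover every disease in the differential")
    }
    if (any(prior_override <= 0 | prior_override >= 1)) {
      abort("prior probabilities must be strictly inside (0, 1)")
    }
  }
  structure(list(age = age, findings = findings,
                 external_tests = external_tests,
                 differential = differential,
                 prior_override = prior_override),
            class = "diagnostic_query")
}

# P(test result | disease): the published sensitivity where the validation
# contrast covers the disease, the inverted sensitivity elsewhere.
test_sens_for <- function(test_row, disease) {
  applies <- test_row$applies_to[[1]]
  if (disease %in% applies) {
    test_row$sensitivity
  } else {
    unname(invert_test(test_row$sensitivity, test_row$specificity)["sensitivity"])
  }
}

test_spec_for <- function(test_row, disease) {
  applies <- test_row$applies_to[[1]]
  if (disease %in% applies) {
    test_row$specificity
  } else {
    unname(invert_test(test_row$sensitivity, test_row$specificity)["specificity"])
  }
}

#' Posterior disease probabilities for a query
#'
#' The naive Bayes diagnostic calculator. Pre-test probabilities come from
#' `prior_override`, else from the age-conditional prior over the
#' differential's onset Gaussians (weights = case-count shares), else are
#' uniform. Each present finding then contributes its positive likelihood
#' ratio and each asserted-absent finding its negative likelihood ratio;
#' external tests contribute [lr_from_test()] ratios, inverted via
#' [invert_test()] for diseases outside the test's validated contrast.
#'
#' Two odds views are computed. `mode = "one_vs_rest"` (canonical): post-test
#' odds(d) = prior odds(d) x product of the findings' d-vs-REST ratios.
#' `mode = "pairwise"`: a per-contrast LR product is reported for every
#' opponent, and the disease's odds multiply the prior odds by all its
#' contrast products. In both modes the per-disease probabilities
#' `odds/(1+odds)` need not sum to 1 across the differential.
#'
#' Separately, a normalised multi-class posterior is computed as exact naive
#' Bayes: prior x product of per-finding likelihoods
#' (frequency if present, complement if absent), normalised to sum to 1.
#' On a synthetic world with conditionally independent findings this equals
#' enumeration Bayes exactly.
#'
#' Diseases whose profile never assessed a queried term (or below the
#' `min_assessed` floor) are dropped from the differential and reported in
#' `$dropped`. Findings whose comparator frequency is zero have an unbounded
#' ratio: by default they are excluded from that disease's product and
#' flagged; with `pathognomonic = TRUE` the ratio is capped at 10^3 (10^-3
#' for the reciprocal).
#'
#' @param query A [diagnostic_query()].
#' @param profiles Named list of `disease_profile`s covering the differential.
#' @param config An [lr_config()].
#' @param mode `"one_vs_rest"` or `"pairwise"`.
#' @param weights Optional named case-count weights for priors and rest
#'   pooling (defaults to profile case counts).
#' @param pathognomonic Cap unbounded ratios instead of excluding them.
#' @return A `diagnostic_result` with `$diseases` (per-disease tibble:
#'   `pre_test_probability`, `total_lr`, `post_test_odds`, `probability`,
#'   `posterior`), `$contrasts` (per-evidence, per-contrast ratios),
#'   `$dropped`, `$excluded_evidence`, plus the query and inputs for
#'   [sequential_update()].
#' @export
posterior <- function(query, profiles, config = lr_config(),
                      mode = c("one_vs_rest", "pairwise"),
                      weights = NULL, pathognomonic = FALSE) {
  mode <- match.arg(mode)
  differential <- query$differential
  missing_profiles <- setdiff(differential, names(profiles))
  if (length(missing_profiles)) {
    abort(paste0("no profile for: ", paste(missing_profiles, collapse = ", ")))
  }
  if (is.null(weights)) {
    weights <- setNames(map_dbl(profiles[differential], "n_cases"), differential)
  }

  # drop diseases that cannot score a queried finding
  dropped <- tibble(disease = character(), reason = character())
  usable <- differential
  for (t in query$findings$term_id) {
    for (d in usable) {
      cts <- profile_counts(profiles[[d]], t)
      if (is.null(cts) || cts$n_assessed < config$min_assessed) {
        dropped <- bind_rows(dropped, tibble(
          disease = d,
          reason = paste0(t, " not assessed (or below min_assessed) in ", d)
        ))
      }
    }
    usable <- setdiff(usable, dropped$disease)
  }
  if (length(usable) == 0L) abort("every disease in the differential was dropped")

  priors <- compute_priors(query, profiles, usable, weights)
  freq <- finding_frequencies(query, profiles, usable, config)

  lr_cap <- 1e3
  excluded <- tibble(disease = character(), evidence = character(),
                     reason = character())
  note_excluded <- function(d, ev, why) {
    excluded <<- bind_rows(excluded, tibble(disease = d, evidence = ev,
                                            reason = why))
  }

  # per-evidence likelihood P(evidence | d) used by the normalised posterior
  lik <- function(d) {
    out <- 1
    for (i in seq_len(nrow(query$findings))) {
      f <- freq[[query$findings$term_id[i]]][[d]]
      out <- out * if (query$findings$status[i] == "present") f else 1 - f
    }
    if (!is.null(query$external_tests)) {
      for (i in seq_len(nrow(query$external_tests))) {
        tr <- query$external_tests[i, ]
        s <- test_sens_for(tr, d)
        out <- out * if (tr$result == "positive") s else 1 - s
      }
    }
    out
  }
  likelihoods <- setNames(map_dbl(usable, lik), usable)
  post_norm <- priors[usable] * likelihoods
  post_norm <- if (sum(post_norm) > 0) post_norm / sum(post_norm) else post_norm

  # one-vs-rest / pairwise ratio for a single piece of evidence
  evidence_lr <- function(d, opponent_freqs, i_finding = NULL, i_test = NULL) {
    if (!is.null(i_finding)) {
      st <- query$findings$status[i_finding]
      t <- query$findings$term_id[i_finding]
      f_d <- freq[[t]][[d]]
      f_o <- opponent_freqs(t)
      num <- if (st == "present") f_d else 1 - f_d
      den <- if (st == "present") f_o else 1 - f_o
      ev <- t
    } else {
      tr <- query$external_tests[i_test, ]
      s_d <- test_sens_for(tr, d)
      s_o <- opponent_freqs(tr)
      num <- if (tr$result == "positive") s_d else 1 - s_d
      den <- if (tr$result == "positive") s_o else 1 - s_o
      ev <- tr$name
    }
    if (den == 0) {
      if (num == 0) return(list(lr = 1, ev = ev))
      if (pathognomonic) return(list(lr = lr_cap, ev = ev))
      note_excluded(d, ev, "unbounded ratio (comparator frequency 0); excluded")
      return(list(lr = NA_real_, ev = ev))
    }
    list(lr = num / den, ev = ev)
  }

  rest_weights <- weights
  contrasts <- tibble(disease_a = character(), disease_b = character(),
                      evidence = character(), lr = numeric())
  total_lr <- setNames(rep(1, length(usable)), usable)

  for (d in usable) {
    if (mode == "one_vs_rest") {
      others <- setdiff(usable, d)
      w <- rest_weights[others] / sum(rest_weights[others])
      opp_f <- function(t_or_test) {
        if (is.character(t_or_test)) {
          sum(w * map_dbl(others, ~ freq[[t_or_test]][[.x]]))
        } else {
          sum(w * map_dbl(others, ~ test_sens_for(t_or_test, .x)))
        }
      }
      pieces <- c(
        map(seq_len(nrow(query$findings)),
            ~ evidence_lr(d, opp_f, i_finding = .x)),
        if (!is.null(query$external_tests)) {
          map(seq_len(nrow(query$external_tests)),
              ~ evidence_lr(d, opp_f, i_test = .x))
        }
      )
      for (p in pieces) {
        contrasts <- bind_rows(contrasts, tibble(
          disease_a = d, disease_b = "REST", evidence = p$ev, lr = p$lr))
        if (!is.na(p$lr)) total_lr[[d]] <- total_lr[[d]] * p$lr
      }
    } else {
      for (o in setdiff(usable, d)) {
        opp_f <- function(t_or_test) {
          if (is.character(t_or_test)) freq[[t_or_test]][[o]]
          else test_sens_for(t_or_test, o)
        }
        pieces <- c(
          map(seq_len(nrow(query$findings)),
              ~ evidence_lr(d, opp_f, i_finding = .x)),
          if (!is.null(query$external_tests)) {
            map(seq_len(nrow(query$external_tests)),
                ~ evidence_lr(d, opp_f, i_test = .x))
          }
        )
        for (p in pieces) {
          contrasts <- bind_rows(contrasts, tibble(
            disease_a = d, disease_b = o, evidence = p$ev, lr = p$lr))
          if (!is.na(p$lr)) total_lr[[d]] <- total_lr[[d]] * p$lr
        }
      }
    }
  }

  pre <- priors[usable]
  prior_odds <- pre / (1 - pre)
  post_odds <- prior_odds * total_lr[usable]
  diseases <- tibble(
    disease = usable,
    pre_test_probability = as.numeric(pre),
    total_lr = as.numeric(total_lr[usable]),
    post_test_odds = as.numeric(post_odds),
    probability = as.numeric(post_odds / (1 + post_odds)),
    posterior = as.numeric(post_norm[usable])
  )

  structure(
    list(diseases = diseases, contrasts = contrasts, dropped = dropped,
         excluded_evidence = excluded, mode = mode, query = query,
         profiles = profiles, config = config, weights = weights,
         pathognomonic = pathognomonic),
    class = "diagnostic_result"
  )
}

compute_priors <- function(query, profiles, usable, weights) {
  if (!is.null(query$prior_override)) {
    return(query$prior_override[usable] / 1)  # used as given, not renormalised
  }
  if (!is.null(query$age)) {
    models <- list()
    for (d in usable) {
      p <- profiles[[d]]
      if (is.null(p$onset) || is.null(p$onset$model)) {
        abort(paste0("no onset model for ", d, "; supply prior_override"))
      }
      models[[d]] <- p$onset$model
    }
    pr <- age_prior(query$age, models, weights[usable])
    return(setNames(pr$prior, pr$disease))
  }
  setNames(rep(1 / length(usable), length(usable)), usable)
}

finding_frequencies <- function(query, profiles, usable, config) {
  out <- list()
  for (t in query$findings$term_id) {
    out[[t]] <- setNames(map(usable, function(d) {
      cts <- profile_counts(profiles[[d]], t)
      if (config$zero_policy == "haldane") {
        (cts$n_present + 0.5) / (cts$n_assessed + 1)
      } else {
        cts$n_present / cts$n_assessed
      }
    }), usable)
  }
  out
}

#' @export
print.diagnostic_result <- function(x, ...) {
  cat("<diagnostic_result> mode =", x$mode, "\n")
  d <- x$diseases
  for (i in order(-d$posterior)) {
    cat(sprintf("  %-5s pre %.2f  total LR %8.3f  odds %8.3f  prob %.2f  posterior %.2f\n",
                d$disease[i], d$pre_test_probability[i], d$total_lr[i],
                d$post_test_odds[i], d$probability[i], d$posterior[i]))
  }
  if (nrow(x$dropped)) {
    cat("  dropped:", paste(unique(x$dropped$disease), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Update a diagnostic result with new evidence
#'
#' Adds one finding or one external test to the query and recomputes the
#' posterior, so the result is identical to having queried with the enlarged
#' evidence set from the start (associativity of the odds products).
#'
#' @param result A `diagnostic_result`.
#' @param finding Optional one-row data frame (`term_id`, `status`).
#' @param test Optional one-row data frame (`name`, `sensitivity`,
#'   `specificity`, `result`, `applies_to` list-column).
#' @return A new `diagnostic_result`.
#' @export
sequential_update <- function(result, finding = NULL, test = NULL) {
  q <- result$query
  if (is.null(finding) && is.null(test)) abort("supply a finding or a test")
  if (!is.null(finding)) {
    finding <- as_tibble(finding)
    if (finding$term_id %in% q$findings$term_id) {
      abort(paste0("duplicate evidence: ", finding$term_id))
    }
    q$findings <- bind_rows(q$findings, finding)
  }
  if (!is.null(test)) {
    test <- as_tibble(test)
    if (!is.null(q$external_tests) && test$name %in% q$external_tests$name) {
      abort(paste0("duplicate evidence: ", test$name))
    }
    q$external_tests <- bind_rows(q$external_tests, test)
  }
  posterior(q, result$profiles, result$config, result$mode, result$weights,
            result$pathognomonic)
}

#' Expected outcome of a screening programme
#'
#' Deterministic expected cell counts when `n` people with disease prevalence
#' `prevalence` are screened with a test of the given sensitivity and
#' specificity: `TP = n * prev * sens`, `FP = n * (1-prev) * (1-spec)`, etc.
#' Counts are expectations and therefore real-valued.
#'
#' @param n Number screened (>= 1).
#' @param prevalence,sensitivity,specificity Proportions in (0, 1).
#' @return A one-row tibble: `n`, `prevalence`, `sensitivity`, `specificity`,
#'   `TP`, `FP`, `FN`, `TN`, `ppv`, `npv`.
#' @export
screening_projection <- function(n, prevalence, sensitivity, specificity) {
  stopifnot(n >= 1, prevalence > 0, prevalence < 1,
            sensitivity > 0, sensitivity < 1,
            specificity > 0, specificity < 1)
  tp <- n * prevalence * sensitivity
  fn <- n * prevalence * (1 - sensitivity)
  fp <- n * (1 - prevalence) * (1 - specificity)
  tn <- n * (1 - prevalence) * specificity
  tibble(n = n, prevalence = prevalence, sensitivity = sensitivity,
         specificity = specificity, TP = tp, FP = fp, FN = fn, TN = tn,
         ppv = tp / (tp + fp), npv = tn / (tn + fn))
}

#' Most informative next observation for a differential pair
#'
#' The inverse query: given two candidate diagnoses, ranks candidate
#' phenotype terms by how much observing them (present or absent) would move
#' the odds — the distance of the term's positive likelihood ratio from the
#' uninformative value 1 on the log10 scale. A ratio of 0.25 is therefore
#' more informative than one of 1.5. Ties break as in
#' [top_discriminators()].
#'
#' @param profiles Named list of `disease_profile`s.
#' @param disease_a,disease_b The diagnostic dilemma.
#' @param candidates Optional term ids to consider (default: every term
#'   assessed in both profiles).
#' @param config An [lr_config()].
#' @return A tibble: `term_id`, `lr_positive`, `abs_log10_lr`, sorted
#'   descending by `abs_log10_lr`.
#' @export
next_best_observation <- function(profiles, disease_a, disease_b,
                                  candidates = NULL, config = lr_config()) {
  pa <- profiles[[disease_a]]
  pb <- profiles[[disease_b]]
  if (is.null(candidates)) {
    candidates <- intersect(pa$phenotype_table$term_id,
                            pb$phenotype_table$term_id)
  }
  rows <- bind_rows(map(candidates, function(t) {
    a <- profile_counts(pa, t)
    b <- profile_counts(pb, t)
    if (is.null(a) || is.null(b) ||
        a$n_assessed < config$min_assessed ||
        b$n_assessed < config$min_assessed) return(NULL)
    lr_row(t, disease_a, disease_b, a$n_present, a$n_assessed,
           b$n_present, b$n_assessed, config)
  }))
  if (nrow(rows) == 0L) {
    return(tibble(term_id = character(), lr_positive = numeric(),
                  abs_log10_lr = numeric()))
  }
  rows <- filter(rows, .data$finite, !is.na(.data$lr_positive),
                 .data$lr_positive > 0)
  rows$abs_log10_lr <- abs(log10(rows$lr_positive))
  ord <- order(-rows$abs_log10_lr,
               -(rows$n_a_assessed + rows$n_b_assessed), rows$term_id)
  select(rows[ord, ], "term_id", "lr_positive", "abs_log10_lr")
}

#' Read a diagnostic query from JSON
#'
#' Accepts the JSON layout
#' `{age, findings: [{term, status}], tests: [{name, sens, spec, result,
#' applies_to}], differential, prior_override}`.
#'
#' @param path JSON file path.
#' @return A [diagnostic_query()].
#' @export
read_query <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  findings <- if (is.null(doc$findings)) NULL else tibble(
    term_id = map_chr(doc$findings, ~ .x$term %||% .x$term_id),
    status = map_chr(doc$findings, "status")
  )
  tests <- if (is.null(doc$tests)) NULL else tibble(
    name = map_chr(doc$tests, "name"),
    sensitivity = map_dbl(doc$tests, ~ as.numeric(.x$sens %||% .x$sensitivity)),
    specificity = map_dbl(doc$tests, ~ as.numeric(.x$spec %||% .x$specificity)),
    result = map_chr(doc$tests, "result"),
    applies_to = map(doc$tests, ~ as.character(unlist(.x$applies_to)))
  )
  diagnostic_query(
    age = doc$age,
    findings = findings,
    external_tests = tests,
    differential = if (is.null(doc$differential)) {
      c("PD", "MSA", "PSP", "DLB", "CBD")
    } else {
      as.character(unlist(doc$differential))
    },
    prior_override = if (is.null(doc$prior_override)) NULL else {
      unlist(doc$prior_override)
    }
  )
}

#' Write a diagnostic result to JSON (full precision) and CSV (2 d.p. view)
#' @param result A `diagnostic_result`.
#' @param dir Output directory.
#' @return Paths written, invisibly.
#' @export
export_result <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  json_path <- file.path(dir, "diagnosis.json")
  jsonlite::write_json(
    list(mode = result$mode,
         diseases = result$diseases,
         contrasts = result$contrasts,
         dropped = result$dropped,
         excluded_evidence = result$excluded_evidence),
    json_path, auto_unbox = TRUE, na = "null", digits = NA, pretty = TRUE
  )
  csv_path <- file.path(dir, "diagnosis_table.csv")
  rounded <- mutate(result$diseases, across(
    c("pre_test_probability", "probability", "posterior"), ~ round(.x, 2)))
  write.csv(rounded, csv_path, row.names = FALSE)
  invisible(c(json_path, csv_path))
}
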