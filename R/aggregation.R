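#' Pool summary statistics across cohorts
#'
#' Combines per-cohort `(mean, sd, n)` summaries into the statistics of the
#' concatenated raw samples: the pooled mean is the sample-size-weighted mean,
#' and the pooled variance combines within-cohort variance with the dispersion
#' of cohort means around the pooled mean. With sample sds (n-1 denominator)
#' in, the result equals `mean()`/`sd()` of the concatenated raw values
#' exactly, which is how the implementation is tested.
#'
#' @param summaries A data frame with columns `mean`, `sd`, `n`, or a list of
#'   [age_summary()] objects. Cohorts with `n = 1` may carry `sd = NA` (they
#'   contribute no within-cohort variance).
#' @return A one-row tibble: `mean`, `sd`, `n_total`, plus a `weights`
#'   list-column holding each cohort's share `n / n_total`.
#' @export
pooled_mean_sd <- function(summaries) {
  s <- as_summary_tibble(summaries)
  if (nrow(s) == 0L) abort("no summaries to pool")
  if (any(!is.na(s$sd) & s$sd < 0)) abort("negative sd in summaries")
  if (any(s$n < 1L)) abort("summary with n < 1")
  n_total <- sum(s$n)
  m <- sum(s$n * s$mean) / n_total
  within <- ifelse(s$n > 1L, (s$n - 1L) * s$sd^2, 0)
  if (any(is.na(within))) abort("sd missing for a cohort with n > 1")
  ss <- sum(within) + sum(s$n * (s$mean - m)^2)
  pooled_sd <- if (n_total > 1L) sqrt(ss / (n_total - 1L)) else 0
  tibble(mean = m, sd = pooled_sd, n_total = n_total,
         weights = list(s$n / n_total))
}

as_summary_tibble <- function(summaries) {
  if (is.data.frame(summaries)) return(as_tibble(summaries))
  summaries <- summaries[!vapply(summaries, is.null, logical(1))]
  tibble(
    mean = map_dbl(summaries, "mean"),
    sd = map_dbl(summaries, "sd"),
    n = map_int(summaries, "n")
  )
}

#' Gaussian onset/survival model
#'
#' A normal density with the pooled empirical mean and standard deviation,
#' evaluated on a fixed support (30-100 years for age of onset, 0-30 years
#' for survival). The density is the plain normal pdf restricted to the
#' support, not renormalised after truncation.
#'
#' @param mean,sd Pooled mean and standard deviation (years; `sd > 0`).
#' @param support Numeric `c(lo, hi)`, `lo < hi`.
#' @return A `gaussian_model` list with fields `mu`, `sigma`, `support`.
#' @export
fit_gaussian <- function(mean, sd, support = c(30, 100)) {
  if (inherits(mean, "data.frame")) {
    sd <- mean$sd[1]
    mean <- mean$mean[1]
  }
  if (is.na(sd) || sd <= 0) abort("cannot fit a Gaussian with sd <= 0")
  stopifnot(length(support) == 2L, support[1] < support[2])
  structure(list(mu = mean, sigma = sd, support = support),
            class = "gaussian_model")
}

#' @export
print.gaussian_model <- function(x, ...) {
  cat(sprintf("<gaussian_model> N(%.2f, %.2f^2) on [%g, %g]\n",
              x$mu, x$sigma, x$support[1], x$support[2]))
  invisible(x)
}

#' Evaluate a Gaussian model density
#' @param model A `gaussian_model`.
#' @param x Ages (years); values outside the support evaluate to 0.
#' @return Density values.
#' @export
model_density <- function(model, x) {
  d <- dnorm(x, model$mu, model$sigma)
  d[x < model$support[1] | x > model$support[2]] <- 0
  d
}

#' Maximum-likelihood age of a Gaussian model
#' @param model A `gaussian_model`.
#' @return The age with maximal density (the mean, clamped to the support).
#' @export
ml_age <- function(model) {
  min(max(model$mu, model$support[1]), model$support[2])
}

#' Survival probability from a Gaussian duration model
#'
#' `P(survival > t)` under the fitted Gaussian disease-duration model:
#' `1 - pnorm(t, mu, sigma)`. At `t = mu` this is 0.5 (the labelled 50%
#' survival point).
#'
#' @param model A `gaussian_model` fitted to disease duration.
#' @param t Years from symptom onset; must lie within the model support.
#' @return Survival probabilities.
#' @export
survival_probability <- function(model, t) {
  if (any(t < model$support[1] | t > model$support[2])) {
    abort("t outside the model support")
  }
  1 - pnorm(t, model$mu, model$sigma)
}

#' Build a per-disease profile from a corpus
#'
#' Pools every cohort of one pathological diagnosis: onset, death and
#' duration summaries are pooled with [pooled_mean_sd()] over the cohorts
#' reporting them, and phenotype counts are summed per term over the cohorts
#' that assessed the term (cohorts not assessing a term contribute nothing —
#' missing is not zero). With `propagate = TRUE` the summed counts are also
#' rolled up to every ancestor term via [aggregate_to_term()].
#'
#' @param corpus A corpus tibble.
#' @param disease Pathological diagnosis code.
#' @param graph Optional `ontology_graph` (required when `propagate = TRUE`).
#' @param propagate Roll counts up the is-a hierarchy.
#' @param aggregate_mode Aggregation mode for propagation (see
#'   [aggregate_to_term()]).
#' @param onset_support,duration_support Gaussian model supports (years).
#' @return A `disease_profile`: disease code, pooled summaries and Gaussian
#'   models for onset/death/duration (NULL when no cohort reports them), a
#'   `phenotype_table` tibble (`term_id`, `n_present`, `n_assessed`,
#'   `propagated`), `n_sources` and `n_cases`.
#' @export
build_profile <- function(corpus, disease, graph = NULL, propagate = FALSE,
                          aggregate_mode = "max",
                          onset_support = c(30, 100),
                          duration_support = c(0, 30)) {
  rows <- filter(corpus, collapse_other(.data$path_diagnosis) ==
                   collapse_other(disease))
  if (nrow(rows) == 0L) abort(paste0("no cohorts with diagnosis ", disease))

  pool_field <- function(field, support) {
    summaries <- rows[[field]][!map_lgl(rows[[field]], is.null)]
    if (length(summaries) == 0L) return(NULL)
    pooled <- pooled_mean_sd(summaries)
    model <- if (pooled$sd > 0) fit_gaussian(pooled$mean, pooled$sd, support)
    list(pooled = pooled, model = model)
  }

  tab <- bind_rows(rows$phenotypes)
  if (nrow(tab) > 0L) {
    tab <- summarise(group_by(tab, .data$term_id),
                     n_present = sum(.data$n_present),
                     n_assessed = sum(.data$n_assessed), .groups = "drop")
    tab$propagated <- FALSE
  } else {
    tab <- mutate(empty_phenotypes(), propagated = logical())
  }
  if (propagate) {
    if (is.null(graph)) abort("propagate = TRUE needs an ontology graph")
    tab <- propagate_counts(tab, graph, aggregate_mode)
  }

  structure(
    list(
      disease = disease,
      onset = pool_field("onset", onset_support),
      death = pool_field("death", onset_support),
      duration = pool_field("duration", duration_support),
      phenotype_table = arrange(tab, .data$term_id),
      n_sources = length(unique(rows$source_id)),
      n_cases = sum(rows$n_cases)
    ),
    class = "disease_profile"
  )
}

propagate_counts <- function(tab, graph, mode) {
  observed <- tab$term_id
  anc <- unique(unlist(lapply(observed, ancestors, graph = graph)))
  targets <- setdiff(anc, observed)
  extra <- bind_rows(lapply(targets, function(t) {
    below <- intersect(observed, c(t, descendants(graph, t)))
    if (length(below) == 0L) return(NULL)
    agg <- aggregate_to_term(tab[tab$term_id %in% below,
                                 c("term_id", "n_present", "n_assessed")],
                             t, graph, mode = mode)
    mutate(agg, propagated = TRUE)
  }))
  # observed terms also absorb their descendants' counts when larger
  direct <- bind_rows(lapply(observed, function(t) {
    below <- intersect(observed, c(t, descendants(graph, t)))
    agg <- aggregate_to_term(tab[tab$term_id %in% below,
                                 c("term_id", "n_present", "n_assessed")],
                             t, graph, mode = mode)
    mutate(agg, propagated = length(below) > 1L)
  }))
  bind_rows(direct, extra)
}

#' @export
print.disease_profile <- function(x, ...) {
  cat("<disease_profile> ", x$disease, ": ", x$n_cases, " cases / ",
      x$n_sources, " sources, ", nrow(x$phenotype_table),
      " phenotype terms\n", sep = "")
  for (f in c("onset", "death", "duration")) {
    if (!is.null(x[[f]])) {
      cat(sprintf("  %-8s %.2f +/- %.2f (n = %d)\n", f, x[[f]]$pooled$mean,
                  x[[f]]$pooled$sd, x[[f]]$pooled$n_total))
    }
  }
  invisible(x)
}

#' Age-conditional disease priors
#'
#' Probability of each disease given an age, from the onset Gaussians and
#' disease weights: `P(d | age) = w_d f_d(age) / sum_e w_e f_e(age)`. By
#' default weights are each disease's share of pooled case counts; pass
#' uniform weights to drop that assumption.
#'
#' @param age Age in years (inside every model's support).
#' @param models Named list of `gaussian_model`s (one per disease).
#' @param weights Named numeric disease weights (any positive scale; only
#'   proportions matter). Defaults to uniform.
#' @return A tibble with columns `disease`, `prior` (summing to 1).
#' @export
age_prior <- function(age, models, weights = NULL) {
  diseases <- names(models)
  if (is.null(weights)) weights <- setNames(rep(1, length(models)), diseases)
  w <- weights[diseases]
  if (any(is.na(w)) || any(w < 0)) abort("weights must cover every model and be >= 0")
  if (sum(w) == 0) abort("weights are all zero")
  dens <- map_dbl(models, model_density, x = age)
  num <- w * dens
  if (sum(num) == 0) abort("age has zero density under every model")
  tibble(disease = diseases, prior = as.numeric(num / sum(num)))
}

#' Rank-based group comparisons of onset/death/duration
#'
#' A Kruskal-Wallis omnibus test across diseases; when significant, pairwise
#' Wilcoxon rank-sum tests with a Bonferroni-style fixed pairwise threshold
#' (default 0.005). Pairwise tests use the exact rank-sum distribution when
#' both groups have at most 25 values and no ties, otherwise the normal
#' approximation with tie and continuity correction.
#'
#' @param data A data frame with columns `group` and `value` (raw per-case
#'   values, e.g. ages of onset by disease).
#' @param alpha_pairwise Pairwise significance threshold.
#' @param alpha_omnibus Omnibus threshold gating the pairwise tests.
#' @return A `group_tests` list: `omnibus` (one-row tibble with `statistic`,
#'   `df`, `p_value`) and `pairwise` (tibble with `group_a`, `group_b`,
#'   `p_value`, `significant`; zero rows when the omnibus is not significant).
#' @export
group_tests <- function(data, alpha_pairwise = 0.005, alpha_omnibus = 0.05) {
  stopifnot(all(c("group", "value") %in% names(data)))
  if (!(alpha_pairwise > 0 && alpha_pairwise < 1)) abort("alpha must be in (0,1)")
  groups <- split(data$value, data$group)
  if (length(groups) < 2L) abort("need at least two groups")
  if (any(lengths(groups) < 2L)) abort("every group needs n >= 2")

  kw <- kruskal.test(groups)
  omnibus <- tibble(statistic = unname(kw$statistic),
                    df = unname(kw$parameter), p_value = kw$p.value)

  pairwise <- tibble(group_a = character(), group_b = character(),
                     p_value = numeric(), significant = logical())
  if (omnibus$p_value < alpha_omnibus) {
    combos <- utils::combn(names(groups), 2L, simplify = FALSE)
    pairwise <- bind_rows(map(combos, function(ab) {
      x <- groups[[ab[1]]]; y <- groups[[ab[2]]]
      exact <- length(x) <= 25L && length(y) <= 25L &&
        !anyDuplicated(c(x, y))
      p <- suppressWarnings(
        wilcox.test(x, y, exact = exact, correct = TRUE)$p.value
      )
      tibble(group_a = ab[1], group_b = ab[2], p_value = p,
             significant = p < alpha_pairwise)
    }))
  }
  structure(list(omnibus = omnibus, pairwise = pairwise,
                 alpha_pairwise = alpha_pairwise),
            class = "group_tests")
}

#' @export
print.group_tests <- function(x, ...) {
  cat(sprintf("<group_tests> Kruskal-Wallis chi^2 = %.3f (df %d), p = %.3g\n",
              x$omnibus$statistic, x$omnibus$df, x$omnibus$p_value))
  if (nrow(x$pairwise)) print(x$pairwise)
  invisible(x)
}

#' Export a disease profile's phenotype table
#' @param profile A `disease_profile`.
#' @param path Optional CSV path.
#' @return The phenotype table tibble.
#' @export
profile_table <- function(profile, path = NULL) {
  out <- mutate(profile$phenotype_table, disease = profile$disease,
                frequency = .data$n_present / .data$n_assessed)
  if (!is.null(path)) write.csv(out, path, row.names = FALSE)
  out
}
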