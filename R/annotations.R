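#' Disease codes used by the annotation format
#'
#' Pathological diagnoses come from a closed set: the five main Parkinsonian
#' proteinopathies, `LBD` (used by studies that do not separate PD from DLB),
#' and an `OTHER:<sublabel>` free-text extension (e.g. `OTHER:AD`,
#' `OTHER:FTD`). Clinical (in-life) labels additionally allow `CBS`
#' (corticobasal syndrome, the in-life presentation of CBD pathology).
#'
#' @param clinical If `TRUE`, return the clinical label set.
#' @return Character vector of the fixed codes (the `OTHER:` extension is
#'   validated by prefix, not enumerated).
#' @export
disease_codes <- function(clinical = FALSE) {
  base <- c("PD", "MSA", "PSP", "DLB", "CBD", "LBD", "OTHER")
  if (clinical) c(base, "CBS") else base
}

valid_disease_code <- function(x, clinical = FALSE) {
  x %in% disease_codes(clinical) | startsWith(x, "OTHER:")
}

#' Collapse OTHER sublabels to the OTHER class
#' @param x Character vector of disease codes.
#' @return Codes with `OTHER:<sublabel>` collapsed to `OTHER`.
#' @export
collapse_other <- function(x) {
  ifelse(startsWith(x, "OTHER"), "OTHER", x)
}

#' Age summary
#'
#' A summarised age (or duration) variable as published: mean, standard
#' deviation and the number of cases summarised, optionally carrying the raw
#' per-case values when a publication lists them. When raw values are given
#' the summary must agree with them (to 1e-9): annotations record what the
#' source printed, and an inconsistent summary is a transcription error.
#'
#' @param mean,sd,n Summary statistics (years; `sd >= 0`, `n >= 1`).
#' @param values Optional numeric vector of raw per-case values.
#' @return An `age_summary` list.
#' @export
age_summary <- function(mean, sd, n, values = NULL) {
  if (is.null(values)) {
    if (missing(mean) || missing(n)) abort("age_summary needs mean and n")
    if (missing(sd) || is.null(sd)) sd <- if (n == 1L) 0 else NA_real_
  } else {
    if (missing(mean)) mean <- base::mean(values)
    if (missing(sd)) sd <- if (length(values) > 1L) stats::sd(values) else 0
    if (missing(n)) n <- length(values)
  }
  s <- structure(
    list(mean = as.numeric(mean), sd = as.numeric(sd), n = as.integer(n),
         values = values),
    class = "age_summary"
  )
  issues <- check_age_summary(s)
  if (length(issues)) abort(issues[1])
  s
}

check_age_summary <- function(s) {
  issues <- character()
  if (s$n < 1L) issues <- c(issues, "age summary n must be >= 1")
  if (!is.na(s$sd) && s$sd < 0) issues <- c(issues, "age summary sd must be >= 0")
  if (!is.null(s$values)) {
    v <- s$values
    if (length(v) != s$n) issues <- c(issues, "raw values length disagrees with n")
    if (abs(base::mean(v) - s$mean) > 1e-9) {
      issues <- c(issues, "raw values disagree with summary mean")
    }
    v_sd <- if (length(v) > 1L) stats::sd(v) else 0
    if (!is.na(s$sd) && abs(v_sd - s$sd) > 1e-9) {
      issues <- c(issues, "raw values disagree with summary sd")
    }
  }
  if (!is.na(s$sd) && s$sd == 0 && s$n > 1L && is.null(s$values)) {
    issues <- c(issues, "sd = 0 with n > 1 and no raw values")
  }
  issues
}

#' @export
print.age_summary <- function(x, ...) {
  cat(sprintf("<age_summary> %.2f +/- %.2f (n = %d%s)\n", x$mean, x$sd, x$n,
              if (!is.null(x$values)) ", raw values" else ""))
  invisible(x)
}

#' Construct a cohort annotation
#'
#' One publication's cohort: the pathological (post-mortem) diagnosis, case
#' counts, optional demographic and timing summaries, an optional in-life
#' diagnosis cross-tab and phenotype observations as
#' `(term_id, n_present, n_assessed)` counts. Fields a publication did not
#' report are absent (`NULL`/`NA`), never zero: a lack of reporting does not
#' equate to an absent sign.
#'
#' @param source_id DOI or PMID of the publication.
#' @param publication_year Integer year (>= 1992).
#' @param cohort_label Label distinguishing cohorts within one publication.
#' @param path_diagnosis Disease code (see [disease_codes()]).
#' @param n_cases Number of post-mortem cases in the cohort.
#' @param n_female,n_male Optional sex counts.
#' @param onset,death,duration Optional [age_summary()] objects (years).
#' @param onset_reference `"symptom_onset"` or `"diagnosis"` — what timings
#'   are measured from.
#' @param clinical_diagnoses Optional data frame with columns `label`,
#'   `count`: final in-life diagnoses cross-tabulated against this cohort's
#'   pathological diagnosis.
#' @param phenotypes Data frame with columns `term_id`, `n_present`,
#'   `n_assessed` (may be empty).
#' @param dual_diagnosis Whether the cohort carries a dual pathological
#'   diagnosis.
#' @param pathology_notes Optional free text.
#' @return A one-row `cohort_annotation` tibble (the corpus row format).
#' @export
cohort_annotation <- function(source_id, publication_year, cohort_label,
                              path_diagnosis, n_cases,
                              n_female = NA_integer_, n_male = NA_integer_,
                              onset = NULL, death = NULL, duration = NULL,
                              onset_reference = "symptom_onset",
                              clinical_diagnoses = NULL,
                              phenotypes = empty_phenotypes(),
                              dual_diagnosis = FALSE,
                              pathology_notes = NA_character_) {
  tibble(
    source_id = as.character(source_id),
    publication_year = as.integer(publication_year),
    cohort_label = as.character(cohort_label),
    path_diagnosis = as.character(path_diagnosis),
    n_cases = as.integer(n_cases),
    n_female = as.integer(n_female),
    n_male = as.integer(n_male),
    onset = list(onset),
    death = list(death),
    duration = list(duration),
    onset_reference = as.character(onset_reference),
    clinical_diagnoses = list(if (is.null(clinical_diagnoses)) NULL else {
      as_tibble(clinical_diagnoses)
    }),
    phenotypes = list(as_tibble(phenotypes)),
    dual_diagnosis = isTRUE(dual_diagnosis),
    pathology_notes = as.character(pathology_notes)
  )
}

empty_phenotypes <- function() {
  tibble(term_id = character(), n_present = integer(), n_assessed = integer())
}

ANNOTATION_FORMAT_VERSION <- "1.0"

#' Read a metaphenomic annotation corpus
#'
#' Reads one annotation JSON file, or every `*.json` file in a directory,
#' into a corpus tibble (one row per cohort, nested list-columns for
#' summaries, cross-tabs and phenotype counts). Rows are ordered by
#' `source_id` then `cohort_label` so corpora load deterministically.
#'
#' Each file holds one publication:
#' `{"format_version": "1.0", "source": {"id", "year"}, "cohorts": [...]}`.
#'
#' @param path A file or directory path.
#' @return A corpus tibble (class `mpa_corpus`).
#' @seealso [write_corpus()], [validate_corpus()], [filter_corpus()]
#' @export
read_corpus <- function(path) {
  files <- if (dir.exists(path)) {
    sort(list.files(path, pattern = "\\.json$", full.names = TRUE))
  } else {
    path
  }
  if (length(files) == 0L) abort(paste0("no annotation JSON files under ", path))
  rows <- bind_rows(map(files, read_annotation_file))
  as_corpus(arrange(rows, .data$source_id, .data$cohort_label))
}

as_corpus <- function(x) {
  class(x) <- unique(c("mpa_corpus", class(x)))
  x
}

read_annotation_file <- function(file) {
  doc <- tryCatch(
    jsonlite::fromJSON(file, simplifyVector = FALSE),
    error = function(e) abort(paste0(file, ": not valid JSON (", conditionMessage(e), ")"))
  )
  need <- function(x, field, where) {
    if (is.null(x[[field]])) {
      abort(paste0(file, ": ", where, " is missing required field \"", field, "\""))
    }
    x[[field]]
  }
  source <- need(doc, "source", "document")
  src_id <- as.character(need(source, "id", "source"))
  year <- as.integer(need(source, "year", "source"))
  cohorts <- need(doc, "cohorts", "document")
  bind_rows(imap(cohorts, function(co, i) {
    where <- paste0("cohort ", i, " of ", src_id)
    cohort_annotation(
      source_id = src_id,
      publication_year = year,
      cohort_label = as.character(need(co, "cohort_label", where)),
      path_diagnosis = as.character(need(co, "path_diagnosis", where)),
      n_cases = as.integer(need(co, "n_cases", where)),
      n_female = co$n_female %||% NA_integer_,
      n_male = co$n_male %||% NA_integer_,
      onset = json_age_summary(co$onset),
      death = json_age_summary(co$death),
      duration = json_age_summary(co$duration),
      onset_reference = co$onset_reference %||% "symptom_onset",
      clinical_diagnoses = if (is.null(co$clinical_diagnoses)) NULL else {
        tibble(
          label = map_chr(co$clinical_diagnoses, "label"),
          count = map_int(co$clinical_diagnoses, ~ as.integer(.x$count))
        )
      },
      phenotypes = if (is.null(co$phenotypes)) empty_phenotypes() else {
        tibble(
          term_id = map_chr(co$phenotypes, "term_id"),
          n_present = map_int(co$phenotypes, ~ as.integer(.x$n_present)),
          n_assessed = map_int(co$phenotypes, ~ as.integer(.x$n_assessed))
        )
      },
      dual_diagnosis = co$dual_diagnosis %||% FALSE,
      pathology_notes = co$pathology_notes %||% NA_character_
    )
  }))
}

json_age_summary <- function(x) {
  if (is.null(x)) return(NULL)
  age_summary(
    mean = x$mean, sd = x$sd %||% NA_real_, n = x$n,
    values = if (is.null(x$values)) NULL else as.numeric(unlist(x$values))
  )
}

#' Write a corpus back to annotation JSON
#'
#' Writes one JSON document per `source_id` into `dir`. `read_corpus()` on the
#' result reproduces the corpus exactly (round-trip identity).
#'
#' @param corpus A corpus tibble.
#' @param dir Output directory (created if needed).
#' @return The paths written, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- map_chr(unique(corpus$source_id), function(src) {
    rows <- filter(corpus, .data$source_id == src)
    doc <- list(
      format_version = ANNOTATION_FORMAT_VERSION,
      source = list(id = src, year = rows$publication_year[1]),
      cohorts = pmap(rows, cohort_to_json)
    )
    path <- file.path(dir, paste0(sanitise_filename(src), ".json"))
    jsonlite::write_json(doc, path, auto_unbox = TRUE, na = "null", digits = NA,
                         pretty = TRUE)
    path
  })
  invisible(paths)
}

sanitise_filename <- function(x) gsub("[^A-Za-z0-9._-]+", "_", x)

cohort_to_json <- function(...) {
  r <- list(...)
  drop_null(list(
    cohort_label = r$cohort_label,
    path_diagnosis = r$path_diagnosis,
    n_cases = r$n_cases,
    n_female = na_null(r$n_female),
    n_male = na_null(r$n_male),
    onset = age_summary_to_json(r$onset),
    death = age_summary_to_json(r$death),
    duration = age_summary_to_json(r$duration),
    onset_reference = r$onset_reference,
    clinical_diagnoses = if (is.null(r$clinical_diagnoses)) NULL else {
      pmap(r$clinical_diagnoses, function(label, count) {
        list(label = label, count = count)
      })
    },
    phenotypes = if (nrow(r$phenotypes) == 0L) NULL else {
      pmap(r$phenotypes, function(term_id, n_present, n_assessed) {
        list(term_id = term_id, n_present = n_present, n_assessed = n_assessed)
      })
    },
    dual_diagnosis = r$dual_diagnosis,
    pathology_notes = na_null(r$pathology_notes)
  ))
}

age_summary_to_json <- function(s) {
  if (is.null(s)) return(NULL)
  drop_null(list(mean = s$mean, sd = na_null(s$sd), n = s$n, values = s$values))
}

na_null <- function(x) if (length(x) == 0L || is.na(x)) NULL else x
drop_null <- function(x) x[!vapply(x, is.null, logical(1))]

#' Validate cohort annotations
#'
#' Checks every invariant of the annotation format and (when an ontology is
#' supplied) that phenotype term ids resolve. Issues are returned, not
#' raised, so a whole corpus can be QC'd in one pass; severity is `"error"`
#' for invariant violations and `"warning"` for suspicious-but-legal content.
#'
#' @param corpus A corpus tibble (or single annotation row).
#' @param graph Optional `ontology_graph` to resolve term ids against.
#' @return A tibble with columns `source_id`, `cohort_label`, `severity`,
#'   `field`, `message` (zero rows when everything passes).
#' @export
validate_corpus <- function(corpus, graph = NULL) {
  out <- bind_rows(pmap(corpus, function(...) {
    r <- list(...)
    issues <- annotation_issues(r, graph)
    if (length(issues) == 0L) return(NULL)
    tibble(
      source_id = r$source_id, cohort_label = r$cohort_label,
      severity = map_chr(issues, 1), field = map_chr(issues, 2),
      message = map_chr(issues, 3)
    )
  }))
  if (nrow(out) == 0L) {
    out <- tibble(source_id = character(), cohort_label = character(),
                  severity = character(), field = character(),
                  message = character())
  }
  out
}

annotation_issues <- function(r, graph) {
  issues <- list()
  err <- function(field, msg) issues[[length(issues) + 1L]] <<- c("error", field, msg)
  wrn <- function(field, msg) issues[[length(issues) + 1L]] <<- c("warning", field, msg)

  if (!valid_disease_code(r$path_diagnosis)) {
    err("path_diagnosis", paste0("unknown disease code: ", r$path_diagnosis))
  }
  if (is.na(r$n_cases) || r$n_cases < 1L) err("n_cases", "n_cases must be >= 1")
  if (!is.na(r$publication_year) && r$publication_year < 1992L) {
    err("publication_year", "publication_year precedes 1992")
  }
  if (!is.na(r$n_female) && !is.na(r$n_male) &&
      r$n_female + r$n_male > r$n_cases) {
    err("n_female", "n_female + n_male exceeds n_cases")
  }
  for (fld in c("onset", "death", "duration")) {
    s <- r[[fld]]
    if (!is.null(s)) {
      for (msg in check_age_summary(s)) err(fld, msg)
      if (s$n > r$n_cases) err(fld, paste0(fld, " n exceeds n_cases"))
    }
  }
  if (!r$onset_reference %in% c("symptom_onset", "diagnosis")) {
    err("onset_reference", paste0("unknown onset_reference: ", r$onset_reference))
  }
  cd <- r$clinical_diagnoses
  if (!is.null(cd) && nrow(cd) > 0L) {
    if (sum(cd$count) > r$n_cases) {
      err("clinical_diagnoses", "clinical diagnosis counts exceed n_cases")
    }
    bad <- cd$label[!valid_disease_code(cd$label, clinical = TRUE)]
    if (length(bad)) {
      err("clinical_diagnoses", paste0("unknown clinical label: ", bad[1]))
    }
  }
  ph <- r$phenotypes
  if (nrow(ph) > 0L) {
    over <- ph$term_id[ph$n_present > ph$n_assessed]
    for (t in over) err("phenotypes", paste0(t, ": n_present > n_assessed"))
    big <- ph$term_id[ph$n_assessed > r$n_cases]
    for (t in big) err("phenotypes", paste0(t, ": n_assessed > n_cases"))
    if (anyDuplicated(ph$term_id)) {
      wrn("phenotypes", "duplicate term_id within one cohort")
    }
    if (!is.null(graph)) {
      missing <- setdiff(ph$term_id, graph$terms$id)
      for (t in missing) err("phenotypes", paste0(t, ": term not in ontology"))
    }
  }
  issues
}

#' Corpus filter specification
#'
#' @param diseases Optional character vector of pathological diagnosis codes
#'   to keep (`OTHER:` sublabels are matched after collapsing to `OTHER`).
#' @param year_range Optional `c(min, max)` publication years, inclusive.
#' @param require_misdiagnosis Keep only cohorts reporting a clinical-vs-
#'   pathological cross-tab (non-empty `clinical_diagnoses`).
#' @param exclude_dual Drop cohorts flagged `dual_diagnosis`.
#' @param split_lbd Drop `LBD` cohorts (studies that do not separate PD from
#'   DLB), keeping only corpora where the two are distinct.
#' @return A `corpus_filter` list.
#' @export
corpus_filter <- function(diseases = NULL, year_range = NULL,
                          require_misdiagnosis = FALSE, exclude_dual = FALSE,
                          split_lbd = FALSE) {
  if (!is.null(year_range)) {
    stopifnot(length(year_range) == 2L, year_range[1] <= year_range[2])
  }
  structure(
    list(diseases = diseases, year_range = year_range,
         require_misdiagnosis = require_misdiagnosis,
         exclude_dual = exclude_dual, split_lbd = split_lbd),
    class = "corpus_filter"
  )
}

#' Filter a corpus for analysis
#'
#' Applies a [corpus_filter()] and returns the matching subset in the original
#' order (idempotent; repeated application is a no-op). `OTHER:<sublabel>`
#' diagnoses are matched against `OTHER` but the sublabels are retained in
#' the data.
#'
#' @param corpus A corpus tibble.
#' @param filter A [corpus_filter()].
#' @return The filtered corpus tibble.
#' @export
filter_corpus <- function(corpus, filter = corpus_filter()) {
  keep <- rep(TRUE, nrow(corpus))
  if (!is.null(filter$diseases)) {
    keep <- keep & collapse_other(corpus$path_diagnosis) %in%
      collapse_other(filter$diseases)
  }
  if (!is.null(filter$year_range)) {
    keep <- keep & corpus$publication_year >= filter$year_range[1] &
      corpus$publication_year <= filter$year_range[2]
  }
  if (isTRUE(filter$require_misdiagnosis)) {
    keep <- keep & map_lgl(corpus$clinical_diagnoses,
                           ~ !is.null(.x) && nrow(.x) > 0L)
  }
  if (isTRUE(filter$exclude_dual)) keep <- keep & !corpus$dual_diagnosis
  if (isTRUE(filter$split_lbd)) keep <- keep & corpus$path_diagnosis != "LBD"
  as_corpus(corpus[keep, , drop = FALSE])
}

#' Flat cohort table for inspection/export
#'
#' Un-nests the corpus into one row per cohort with scalar columns only
#' (summary means/sds, counts), suitable for CSV export.
#'
#' @param corpus A corpus tibble.
#' @param path Optional CSV path; when given the table is also written there.
#' @return A flat tibble.
#' @export
corpus_table <- function(corpus, path = NULL) {
  pick <- function(col, what) {
    map_dbl(corpus[[col]], ~ if (is.null(.x)) NA_real_ else .x[[what]])
  }
  out <- tibble(
    source_id = corpus$source_id,
    publication_year = corpus$publication_year,
    cohort_label = corpus$cohort_label,
    path_diagnosis = corpus$path_diagnosis,
    n_cases = corpus$n_cases,
    n_female = corpus$n_female,
    n_male = corpus$n_male,
    onset_mean = pick("onset", "mean"), onset_sd = pick("onset", "sd"),
    onset_n = pick("onset", "n"),
    death_mean = pick("death", "mean"), death_sd = pick("death", "sd"),
    duration_mean = pick("duration", "mean"), duration_sd = pick("duration", "sd"),
    onset_reference = corpus$onset_reference,
    n_misdiagnosis_cases = map_dbl(corpus$clinical_diagnoses,
                                   ~ if (is.null(.x)) NA_real_ else sum(.x$count)),
    n_phenotype_terms = map_int(corpus$phenotypes, nrow),
    dual_diagnosis = corpus$dual_diagnosis
  )
  if (!is.null(path)) write.csv(out, path, row.names = FALSE)
  out
}

#' Published corpus bookkeeping
#'
#' Per-diagnosis post-mortem case counts of the published clinicopathological
#' corpus this package's annotation format was designed around: the full
#' 125-publication corpus used for onset and survival analyses, and the
#' subset that reported clinical-vs-pathological misdiagnosis data. These are
#' the default case-count weights for age-based priors; they are reference
#' numbers, not data this package can recompute (the underlying database is
#' distributed separately).
#'
#' @return A tibble with columns `disease`, `n_cases` (full corpus) and
#'   `n_cases_misdiagnosis` (misdiagnosis subset).
#' @seealso [published_sex_reporting()]
#' @export
published_case_counts <- function() {
  tibble(
    disease = c("PD", "MSA", "PSP", "DLB", "CBD", "OTHER"),
    n_cases = c(2406L, 1594L, 1835L, 834L, 354L, 2264L),
    n_cases_misdiagnosis = c(1698L, 965L, 1349L, 347L, 265L, 1124L)
  )
}

#' @rdname published_case_counts
#' @return `published_sex_reporting()`: a one-row tibble with `n_reported`
#'   (cases whose publications reported biological sex) and the full-corpus
#'   denominator `n_total`.
#' @export
published_sex_reporting <- function() {
  tibble(n_reported = 4341L, n_total = sum(published_case_counts()$n_cases))
}
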