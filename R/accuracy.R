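DEFAULT_CONFUSION_LABELS <- c("PD", "MSA", "PSP", "DLB", "CBD", "OTHER")

#' Clinical-vs-pathological confusion matrix
#'
#' Cross-tabulates final in-life diagnoses (rows, the "prediction") against
#' post-mortem pathological diagnoses (columns, the ground truth) over every
#' cohort that reports misdiagnosis data. Labels outside `labels` fold into
#' `OTHER`; with `cbs_equals_cbd = TRUE` the in-life label CBS (corticobasal
#' syndrome) is counted as clinical CBD, since CBD pathology presents as CBS
#' in life.
#'
#' @param corpus A corpus tibble (cohorts without a cross-tab are skipped; use
#'   [filter_corpus()] with `require_misdiagnosis = TRUE` to make that
#'   explicit).
#' @param labels Ordered disease codes for rows/columns.
#' @param cbs_equals_cbd Merge clinical CBS into CBD.
#' @return A `confusion_matrix`: list with `labels` and an integer `counts`
#'   matrix indexed `[clinical, pathological]`.
#' @export
build_confusion <- function(corpus, labels = DEFAULT_CONFUSION_LABELS,
                            cbs_equals_cbd = TRUE) {
  counts <- matrix(0L, length(labels), length(labels),
                   dimnames = list(clinical = labels, pathological = labels))
  for (i in seq_len(nrow(corpus))) {
    cd <- corpus$clinical_diagnoses[[i]]
    if (is.null(cd) || nrow(cd) == 0L) next
    if (sum(cd$count) > corpus$n_cases[i]) {
      abort(paste0(corpus$source_id[i], " / ", corpus$cohort_label[i],
                   ": clinical diagnosis counts exceed n_cases"))
    }
    p <- fold_label(corpus$path_diagnosis[i], labels, cbs_equals_cbd)
    for (j in seq_len(nrow(cd))) {
      cl <- fold_label(cd$label[j], labels, cbs_equals_cbd)
      counts[cl, p] <- counts[cl, p] + cd$count[j]
    }
  }
  structure(list(labels = labels, counts = counts), class = "confusion_matrix")
}

fold_label <- function(x, labels, cbs_equals_cbd) {
  x <- collapse_other(x)
  if (cbs_equals_cbd && x == "CBS") x <- "CBD"
  if (!x %in% labels) x <- "OTHER"
  x
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("<confusion_matrix> clinical (rows) x pathological (columns), n =",
      sum(x$counts), "\n")
  print(x$counts)
  invisible(x)
}

#' One-vs-rest diagnostic performance for one disease
#'
#' Collapses the K-way confusion matrix to a 2x2 table for one disease:
#' TP = correctly labelled cases of the disease, FN = its pathological cases
#' labelled otherwise in life, FP = other pathologies labelled as the disease,
#' TN = the remainder. Sensitivity, specificity and balanced accuracy follow.
#'
#' @param cm A `confusion_matrix`.
#' @param disease A label present in the matrix.
#' @return A one-row tibble: `disease`, `TP`, `FP`, `FN`, `TN`,
#'   `sensitivity`, `specificity`, `balanced_accuracy`.
#' @export
binary_performance <- function(cm, disease) {
  if (!disease %in% cm$labels) abort(paste0("unknown label: ", disease))
  m <- cm$counts
  if (sum(m[, disease]) == 0L) {
    abort(paste0("no pathological cases of ", disease, " in the matrix"))
  }
  tp <- m[disease, disease]
  fn <- sum(m[, disease]) - tp
  fp <- sum(m[disease, ]) - tp
  tn <- sum(m) - tp - fn - fp
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  tibble(disease = disease, TP = tp, FP = fp, FN = fn, TN = tn,
         sensitivity = sens, specificity = spec,
         balanced_accuracy = (sens + spec) / 2)
}

#' Misdiagnosis and missed-diagnosis rate matrices
#'
#' `direction = "clinical_to_path"` normalises each clinical row: of the
#' cases given a clinical label, what fraction had each pathology
#' (misdiagnosis view). `direction = "path_to_clinical"` normalises each
#' pathological column: of the cases with a pathology, what clinical labels
#' were they given (missed-diagnosis view). Vectors with a zero margin are
#' undefined and returned as `NA`, never 0.
#'
#' @param cm A `confusion_matrix`.
#' @param direction Normalisation direction.
#' @return A numeric matrix of proportions with the same dimnames.
#' @export
misdiagnosis_rates <- function(cm, direction = c("clinical_to_path",
                                                 "path_to_clinical")) {
  direction <- match.arg(direction)
  m <- cm$counts
  out <- matrix(NA_real_, nrow(m), ncol(m), dimnames = dimnames(m))
  if (direction == "clinical_to_path") {
    margins <- rowSums(m)
    for (i in seq_len(nrow(m))) {
      if (margins[i] > 0) out[i, ] <- m[i, ] / margins[i]
    }
  } else {
    margins <- colSums(m)
    for (j in seq_len(ncol(m))) {
      if (margins[j] > 0) out[, j] <- m[, j] / margins[j]
    }
  }
  out
}

#' Balanced accuracy over publication-year windows
#'
#' Partitions the corpus's publication-year range into consecutive windows of
#' `window_years` and recomputes one disease's balanced accuracy within each,
#' to expose drift in diagnostic accuracy over time. Windows with no
#' cross-tabulated pathological cases of the disease are omitted.
#'
#' @param corpus A corpus tibble.
#' @param disease Disease code.
#' @param window_years Window width in years (>= 1).
#' @param labels Confusion labels (see [build_confusion()]).
#' @param cbs_equals_cbd Merge clinical CBS into CBD.
#' @return A tibble: `window_start`, `window_end`, `balanced_accuracy`, `n`
#'   (cross-tabulated cases in the window).
#' @export
accuracy_timeline <- function(corpus, disease, window_years = 5,
                              labels = DEFAULT_CONFUSION_LABELS,
                              cbs_equals_cbd = TRUE) {
  if (window_years < 1) abort("window_years must be >= 1")
  has_xtab <- map_lgl(corpus$clinical_diagnoses, ~ !is.null(.x) && nrow(.x) > 0L)
  corpus <- corpus[has_xtab, , drop = FALSE]
  if (nrow(corpus) == 0L) {
    return(tibble(window_start = integer(), window_end = integer(),
                  balanced_accuracy = numeric(), n = integer()))
  }
  y0 <- min(corpus$publication_year)
  y1 <- max(corpus$publication_year)
  starts <- seq(y0, y1, by = window_years)
  bind_rows(map(starts, function(ws) {
    we <- ws + window_years - 1L
    sub <- corpus[corpus$publication_year >= ws & corpus$publication_year <= we, ]
    if (nrow(sub) == 0L) return(NULL)
    cm <- build_confusion(sub, labels, cbs_equals_cbd)
    if (sum(cm$counts[, disease]) == 0L) return(NULL)
    perf <- binary_performance(cm, disease)
    tibble(window_start = as.integer(ws), window_end = as.integer(we),
           balanced_accuracy = perf$balanced_accuracy,
           n = as.integer(sum(cm$counts)))
  }))
}

#' Export a confusion matrix and per-disease performance to CSV
#' @param cm A `confusion_matrix`.
#' @param dir Output directory.
#' @return Paths written, invisibly.
#' @export
export_confusion <- function(cm, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mat_path <- file.path(dir, "confusion_matrix.csv")
  write.csv(cm$counts, mat_path, row.names = TRUE)
  with_cases <- cm$labels[colSums(cm$counts) > 0]
  perf <- bind_rows(map(with_cases, binary_performance, cm = cm))
  perf_path <- file.path(dir, "binary_performance.csv")
  write.csv(perf, perf_path, row.names = FALSE)
  invisible(c(mat_path, perf_path))
}
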