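# Shared fixtures: everything is built in code at test time.

# 4-term fixture: root A; B is-a A; C is-a B; D is-a B
tiny_obo <- function(extra = "") {
  txt <- paste(
    "format-version: 1.2",
    "", "[Term]", "id: T:A", "name: root",
    "", "[Term]", "id: T:B", "name: b", "is_a: T:A",
    "", "[Term]", "id: T:C", "name: c", "is_a: T:B",
    "", "[Term]", "id: T:D", "name: d", "is_a: T:B",
    extra,
    sep = "\n")
  path <- withr::local_tempfile(fileext = ".obo", .local_envir = parent.frame())
  writeLines(txt, path)
  path
}

tiny_graph <- function() parse_ontology(tiny_obo())

mini_graph <- function() {
  parse_ontology(system.file("extdata", "mini_parkinsonism_hpo.obo",
                             package = "metaphen"))
}

example_corpus <- function() {
  read_corpus(system.file("extdata", "example_corpus_synthetic",
                          package = "metaphen"))
}

# random parent-list DAG over n nodes: node i may only point at nodes < i,
# guaranteeing acyclicity; returns an ontology_graph via a temp OBO file
random_dag_graph <- function(n = 50, p_edge = 0.08) {
  ids <- sprintf("T:%03d", seq_len(n))
  stanzas <- vapply(seq_len(n), function(i) {
    parents <- if (i == 1L) character() else {
      ids[seq_len(i - 1L)][runif(i - 1L) < p_edge]
    }
    paste(c("", "[Term]", paste0("id: ", ids[i]), paste0("name: node ", i),
            paste0("is_a: ", parents)), collapse = "\n")
  }, character(1))
  path <- withr::local_tempfile(fileext = ".obo", .local_envir = parent.frame())
  writeLines(paste0("format-version: 1.2\n", paste(stanzas, collapse = "\n")),
             path)
  parse_ontology(path)
}

# brute-force ancestor closure by path enumeration (independent of closure())
brute_ancestors <- function(graph, id) {
  out <- character()
  walk <- function(v) {
    for (p in graph$parents[[v]]) {
      out <<- c(out, p)
      walk(p)
    }
  }
  walk(id)
  sort(unique(out))
}

# single-cohort profile with exact phenotype frequencies (counts over n)
exact_profile <- function(disease, freqs, n = 1000L,
                          onset = c(60, 10), duration = c(10, 3)) {
  counts <- round(freqs * n)
  stopifnot(all(abs(counts - freqs * n) < 1e-9))
  ann <- cohort_annotation(
    source_id = paste0("EXACT:", disease), publication_year = 2000L,
    cohort_label = "c1", path_diagnosis = disease, n_cases = n,
    onset = age_summary(mean = onset[1], sd = onset[2], n = n),
    duration = age_summary(mean = duration[1], sd = duration[2], n = n),
    phenotypes = tibble::tibble(
      term_id = names(freqs), n_present = as.integer(counts),
      n_assessed = rep(n, length(freqs))
    )
  )
  build_profile(ann, disease)
}

# confusion_matrix from a raw counts matrix (clinical x pathological)
confusion_from_counts <- function(m) {
  structure(list(labels = rownames(m), counts = m), class = "confusion_matrix")
}
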