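#' Parse a phenotype ontology
#'
#' Reads an ontology from either an OBO 1.2 flat file or an ontology-graph
#' JSON document (objects with `nodes` and `edges` arrays) and returns an
#' `ontology_graph` restricted to is-a relationships. Terms flagged obsolete
#' are retained but marked, and their `replaced_by` target (when present) is
#' kept so curated mappings can be redirected across ontology releases.
#'
#' Only is-a edges are loaded; all other relationship types (part-of,
#' regulates, ...) are ignored, so the graph is the plain subsumption
#' hierarchy used for count propagation and likelihood-ratio searches.
#'
#' @param path Path to the ontology file.
#' @param format `"obo"` or `"graph-json"`. Defaults to a guess from the file
#'   extension (`.obo` vs `.json`).
#' @return An `ontology_graph`: a list with `terms` (a tibble with columns
#'   `id`, `name`, `obsolete`, `replaced_by`), `parents` (named list of
#'   character vectors of parent ids) and `roots` (ids with no parents).
#' @examples
#' obo <- system.file("extdata", "mini_parkinsonism_hpo.obo", package = "metaphen")
#' g <- parse_ontology(obo)
#' g$roots
#' @export
parse_ontology <- function(path, format = c("auto", "obo", "graph-json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "graph-json" else "obo"
  }
  raw <- switch(format,
    "obo" = parse_obo_stanzas(readLines(path, warn = FALSE)),
    "graph-json" = parse_graph_json(path)
  )
  new_ontology_graph(raw$terms, raw$parents)
}

# Minimal OBO 1.2 reader: [Term] stanzas with id / name / is_a / is_obsolete /
# replaced_by tags. Trailing "! comment" text after an id is stripped.
parse_obo_stanzas <- function(lines) {
  lines <- trimws(lines)
  stanza_starts <- which(lines == "[Term]")
  if (length(stanza_starts) == 0L) {
    abort("no [Term] stanzas found; is this an OBO file?")
  }
  other_headers <- which(grepl("^\\[", lines) & lines != "[Term]")
  bounds <- c(stanza_starts, other_headers, length(lines) + 1L)
  terms <- vector("list", length(stanza_starts))
  for (i in seq_along(stanza_starts)) {
    s <- stanza_starts[i]
    e <- min(bounds[bounds > s]) - 1L
    block <- lines[seq(s + 1L, e)]
    tag_val <- function(tag) {
      hits <- block[startsWith(block, paste0(tag, ":"))]
      vals <- sub(paste0("^", tag, ":\\s*"), "", hits)
      sub("\\s*!.*$", "", vals)
    }
    id <- tag_val("id")
    if (length(id) != 1L) abort("OBO [Term] stanza without exactly one id")
    nm <- tag_val("name")
    repl <- tag_val("replaced_by")
    terms[[i]] <- list(
      id = id,
      name = if (length(nm)) nm[1] else id,
      parent_ids = tag_val("is_a"),
      obsolete = any(tolower(tag_val("is_obsolete")) == "true"),
      replaced_by = if (length(repl)) repl[1] else NA_character_
    )
  }
  list(
    terms = tibble(
      id = map_chr(terms, "id"),
      name = map_chr(terms, "name"),
      obsolete = map_lgl(terms, "obsolete"),
      replaced_by = map_chr(terms, "replaced_by")
    ),
    parents = setNames(map(terms, "parent_ids"), map_chr(terms, "id"))
  )
}

parse_graph_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  graph <- if (!is.null(doc$graphs)) doc$graphs[1, , drop = FALSE] else doc
  nodes <- as_tibble(if (!is.null(doc$graphs)) graph$nodes[[1]] else graph$nodes)
  edges <- as_tibble(if (!is.null(doc$graphs)) graph$edges[[1]] else graph$edges)
  if (!all(c("sub", "obj") %in% names(edges)) && all(c("child", "parent") %in% names(edges))) {
    edges <- rename(edges, sub = "child", obj = "parent")
  }
  if (!"pred" %in% names(edges)) edges$pred <- "is_a"
  edges <- filter(edges, .data$pred %in% c("is_a", "is-a", "subClassOf"))
  name_col <- intersect(c("lbl", "name", "label"), names(nodes))[1]
  obsolete <- rep(FALSE, nrow(nodes))
  if ("meta" %in% names(nodes) && !is.null(nodes$meta$deprecated)) {
    obsolete <- isTRUE_vec(nodes$meta$deprecated)
  } else if ("obsolete" %in% names(nodes)) {
    obsolete <- isTRUE_vec(nodes$obsolete)
  }
  ids <- nodes$id
  list(
    terms = tibble(
      id = ids,
      name = if (!is.na(name_col)) as.character(nodes[[name_col]]) else ids,
      obsolete = obsolete,
      replaced_by = if ("replaced_by" %in% names(nodes)) {
        as.character(nodes$replaced_by)
      } else {
        rep(NA_character_, length(ids))
      }
    ),
    parents = lapply(setNames(ids, ids), function(i) edges$obj[edges$sub == i])
  )
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

new_ontology_graph <- function(terms, parents) {
  ids <- terms$id
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate term id: ", ids[duplicated(ids)][1]))
  }
  parents <- lapply(parents, function(p) unique(p[!is.na(p) & nzchar(p)]))
  dangling <- setdiff(unlist(parents, use.names = FALSE), ids)
  if (length(dangling)) {
    abort(paste0("dangling parent reference: ", dangling[1]))
  }
  assert_acyclic(parents, ids)
  g <- structure(
    list(
      terms = terms,
      parents = parents[ids],
      roots = ids[lengths(parents[ids]) == 0L & !terms$obsolete]
    ),
    class = "ontology_graph"
  )
  g
}

# Kahn's algorithm over child -> parent edges; leftovers imply a cycle.
assert_acyclic <- function(parents, ids) {
  out_deg <- lengths(parents[ids])
  names(out_deg) <- ids
  children <- invert_parents(parents)
  queue <- ids[out_deg == 0L]
  seen <- 0L
  while (length(queue)) {
    v <- queue[[1]]
    queue <- queue[-1]
    seen <- seen + 1L
    for (ch in children[[v]]) {
      out_deg[[ch]] <- out_deg[[ch]] - 1L
      if (out_deg[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (seen < length(ids)) {
    bad <- names(out_deg)[out_deg > 0L][1]
    abort(paste0("ontology contains a cycle involving term ", bad))
  }
  invisible(TRUE)
}

invert_parents <- function(parents) {
  children <- lapply(parents, function(.) character())
  for (ch in names(parents)) {
    for (p in parents[[ch]]) children[[p]] <- c(children[[p]], ch)
  }
  children
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat("<ontology_graph> ", nrow(x$terms), " terms, ",
      sum(x$terms$obsolete), " obsolete, roots: ",
      paste(x$roots, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Is-a closure queries
#'
#' `ancestors()` returns the transitive is-a closure above a term (excluding
#' the term itself); `descendants()` the closure below it. Both return a
#' deterministic (sorted) character vector of term ids.
#'
#' @param graph An `ontology_graph`.
#' @param id A term CURIE present in the graph.
#' @return Character vector of term ids (possibly empty).
#' @export
ancestors <- function(graph, id) {
  closure(graph$parents, graph, id)
}

#' @rdname ancestors
#' @export
descendants <- function(graph, id) {
  closure(invert_parents(graph$parents), graph, id)
}

closure <- function(adj, graph, id) {
  if (!id %in% graph$terms$id) abort(paste0("unknown term id: ", id))
  seen <- character()
  queue <- adj[[id]]
  while (length(queue)) {
    v <- queue[[1]]
    queue <- queue[-1]
    if (!v %in% seen) {
      seen <- c(seen, v)
      queue <- c(queue, adj[[v]])
    }
  }
  sort(unique(seen))
}

#' Aggregate phenotype counts up the hierarchy
#'
#' Combines cohort-level `(n_present, n_assessed)` observations recorded on a
#' target term or its descendants into a single count pair for the target.
#' Because cohort counts do not identify individual cases, sibling counts
#' cannot be unioned: `mode = "max"` takes the largest `n_present` among
#' contributors (a conservative lower bound on the parent-term frequency),
#' while `mode = "capped_sum"` sums `n_present` capped at the largest
#' `n_assessed` (an upper bound that may double-count patients reported under
#' several sibling terms).
#'
#' @param observations Data frame with columns `term_id`, `n_present`,
#'   `n_assessed`; every `term_id` must be `target` or one of its descendants.
#' @param target Target term CURIE.
#' @param graph An `ontology_graph`.
#' @param mode `"max"` (default) or `"capped_sum"`.
#' @return A one-row tibble with `term_id`, `n_present`, `n_assessed`.
#' @export
aggregate_to_term <- function(observations, target, graph,
                              mode = c("max", "capped_sum")) {
  mode <- match.arg(mode)
  obs <- as_tibble(observations)
  if (nrow(obs) == 0L) abort("no observations to aggregate")
  if (any(obs$n_present > obs$n_assessed)) {
    abort("n_present exceeds n_assessed in an observation")
  }
  allowed <- c(target, descendants(graph, target))
  outside <- setdiff(obs$term_id, allowed)
  if (length(outside)) {
    abort(paste0("observation term outside subtree of ", target, ": ", outside[1]))
  }
  n_assessed <- max(obs$n_assessed)
  n_present <- switch(mode,
    max = max(obs$n_present),
    capped_sum = min(sum(obs$n_present), n_assessed)
  )
  tibble(term_id = target, n_present = n_present, n_assessed = n_assessed)
}

#' Curated label-to-term mappings
#'
#' `term_mapping()` validates a curated table mapping free-text source
#' descriptors (as printed in publications) to ontology term ids;
#' `map_label()` looks a label up with exact, case-insensitive,
#' whitespace-normalised matching — no fuzzy matching, so curation stays the
#' single source of truth.
#'
#' Obsolete terms are accepted in a mapping only via their `replaced_by`
#' target, which is substituted silently; obsolete terms without a
#' replacement are rejected.
#'
#' @param mapping Data frame with columns `source_label`, `term_id`.
#' @param graph An `ontology_graph` the term ids must resolve in.
#' @param label Free-text label to look up.
#' @return `term_mapping()`: the validated mapping tibble (with normalised
#'   labels and redirected term ids). `map_label()`: a single term CURIE.
#' @export
term_mapping <- function(mapping, graph) {
  m <- as_tibble(mapping)
  m$source_label <- normalise_label(m$source_label)
  if (anyDuplicated(m$source_label)) {
    abort(paste0("duplicate source_label in mapping: ",
                 m$source_label[duplicated(m$source_label)][1]))
  }
  unknown <- setdiff(m$term_id, graph$terms$id)
  if (length(unknown)) abort(paste0("mapping term not in ontology: ", unknown[1]))
  info <- graph$terms[match(m$term_id, graph$terms$id), ]
  redirect <- info$obsolete & !is.na(info$replaced_by)
  m$term_id[redirect] <- info$replaced_by[redirect]
  still_obsolete <- graph$terms$obsolete[match(m$term_id, graph$terms$id)]
  if (any(still_obsolete)) {
    abort(paste0("mapping targets obsolete term without replacement: ",
                 m$term_id[still_obsolete][1]))
  }
  structure(m, class = c("term_mapping", class(m)))
}

#' @rdname term_mapping
#' @export
map_label <- function(label, mapping) {
  key <- normalise_label(label)
  hit <- match(key, mapping$source_label)
  if (is.na(hit)) abort(paste0("unmapped label: \"", label, "\""))
  mapping$term_id[hit]
}

normalise_label <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}

#' Serialise an ontology graph to graph JSON
#'
#' Writes the nodes/edges representation read back by
#' [parse_ontology()] with `format = "graph-json"`.
#'
#' @param graph An `ontology_graph`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ontology_json <- function(graph, path) {
  edges <- bind_rows(imap(graph$parents, function(p, id) {
    if (length(p)) tibble(sub = id, pred = "is_a", obj = p) else NULL
  }))
  doc <- list(
    nodes = graph$terms[, c("id", "name", "obsolete", "replaced_by")],
    edges = edges
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, na = "null", digits = NA)
  invisible(path)
}
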