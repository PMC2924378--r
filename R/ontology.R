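#' Parse an OBO ontology into a term graph
#'
#' Reads OBO 1.2/1.4 flat-file text and builds a directed acyclic term graph
#' with edges pointing from child terms to parent terms, restricted to a
#' single namespace. Obsolete terms are dropped, and only edges whose
#' relation label is in `relations` are kept (the `is_a` backbone by
#' default; `part_of` and others can be admitted explicitly). Edges whose
#' parent falls outside the retained term set (e.g. in another namespace)
#' are dropped.
#'
#' @param file Path to an OBO file, or a character vector of OBO lines.
#' @param namespace Namespace to restrict to (`"biological_process"`,
#'   `"molecular_function"` or `"cellular_component"`), or `NULL` to keep
#'   every namespace. Stanzas with no namespace tag are kept only when
#'   `namespace` is `NULL`.
#' @param relations Character vector of relation labels to retain as edges.
#'   `"is_a"` is always a valid label; other labels refer to
#'   `relationship:` tags.
#' @return An object of class `ontology_graph`: a list with elements
#'   `graph` (an igraph, child-to-parent), `records` (data frame of
#'   id/name/namespace), `namespace`, and `n_dropped_edges`.
#' @examples
#' obo <- c("[Term]", "id: GO:1", "name: root",
#'          "[Term]", "id: GO:2", "name: child", "is_a: GO:1")
#' g <- parse_obo(obo)
#' pair_distance(g, "GO:2", "GO:1")
#' @export
parse_obo <- function(file, namespace = NULL, relations = "is_a") {
  lines <- if (length(file) == 1L && !grepl("\n", file) && file.exists(file)) {
    readLines(file, warn = FALSE)
  } else {
    unlist(strsplit(file, "\n", fixed = TRUE), use.names = FALSE)
  }
  stanza_starts <- which(trimws(lines) == "[Term]")
  other_stanzas <- which(grepl("^\\[", trimws(lines)) & trimws(lines) != "[Term]")
  records <- vector("list", length(stanza_starts))
  edges <- vector("list", length(stanza_starts))
  for (i in seq_along(stanza_starts)) {
    from <- stanza_starts[i] + 1L
    bounds <- c(stanza_starts[stanza_starts > stanza_starts[i]],
                other_stanzas[other_stanzas > stanza_starts[i]])
    to <- if (length(bounds)) min(bounds) - 1L else length(lines)
    stanza <- .parse_term_stanza(lines[from:to], from)
    if (is.null(stanza$id)) {
      stop("malformed [Term] stanza at line ", stanza_starts[i], ": missing id tag")
    }
    records[[i]] <- stanza
    if (!isTRUE(stanza$obsolete) && nrow(stanza$parents)) {
      edges[[i]] <- cbind(child = stanza$id, stanza$parents)
    }
  }
  rec <- data.frame(
    id = vapply(records, `[[`, "", "id"),
    name = vapply(records, function(r) r$name %||% "", ""),
    namespace = vapply(records, function(r) r$namespace %||% NA_character_, ""),
    obsolete = vapply(records, function(r) isTRUE(r$obsolete), NA),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(rec$id)) {
    stop("duplicate term id in OBO input: ", rec$id[duplicated(rec$id)][1])
  }
  keep <- !rec$obsolete
  if (!is.null(namespace)) keep <- keep & !is.na(rec$namespace) & rec$namespace == namespace
  rec <- rec[keep, , drop = FALSE]
  edf <- do.call(rbind, edges)
  edf <- if (is.null(edf)) {
    data.frame(child = character(), parent = character(), relation = character())
  } else {
    data.frame(child = edf[, "child"], parent = edf[, "parent"],
               relation = edf[, "relation"], stringsAsFactors = FALSE)
  }
  edf <- edf[edf$relation %in% relations, , drop = FALSE]
  in_graph <- edf$child %in% rec$id & edf$parent %in% rec$id
  n_dropped <- sum(!in_graph)
  edf <- edf[in_graph, , drop = FALSE]
  .new_ontology_graph(rec, edf, namespace %||% "all", n_dropped)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.parse_term_stanza <- function(lines, first_line_no) {
  out <- list(id = NULL, name = NULL, namespace = NULL, obsolete = FALSE,
              parents = data.frame(parent = character(), relation = character()))
  par_parent <- character()
  par_rel <- character()
  for (j in seq_along(lines)) {
    ln <- trimws(sub("!.*$", "", lines[j]))
    if (ln == "") next
    m <- regmatches(ln, regexec("^([A-Za-z_]+):\\s*(.*)$", ln))[[1]]
    if (length(m) != 3L) {
      stop("malformed OBO tag line at line ", first_line_no + j - 1L, ": ", lines[j])
    }
    tag <- m[2]; val <- trimws(m[3])
    if (tag == "id") out$id <- val
    else if (tag == "name") out$name <- val
    else if (tag == "namespace") out$namespace <- val
    else if (tag == "is_obsolete") out$obsolete <- identical(tolower(val), "true")
    else if (tag == "is_a") { par_parent <- c(par_parent, val); par_rel <- c(par_rel, "is_a") }
    else if (tag == "relationship") {
      parts <- strsplit(val, "\\s+")[[1]]
      if (length(parts) < 2L) {
        stop("malformed relationship tag at line ", first_line_no + j - 1L, ": ", lines[j])
      }
      par_parent <- c(par_parent, parts[2]); par_rel <- c(par_rel, parts[1])
    }
  }
  out$parents <- data.frame(parent = par_parent, relation = par_rel,
                            stringsAsFactors = FALSE)
  out
}

#' Read a child-parent edge list as an ontology graph
#'
#' Accepts the two-column TSV alternative to OBO used for small fixtures:
#' one header line, then `child<TAB>parent` rows. Terms are the union of
#' both columns; all edges are treated as `is_a`.
#'
#' @param file Path to the TSV file.
#' @param namespace Namespace label to record on the graph.
#' @return An `ontology_graph`.
#' @export
read_edge_tsv <- function(file, namespace = "biological_process") {
  df <- utils::read.delim(file, header = TRUE, colClasses = "character")
  if (ncol(df) < 2L) stop("edge list must have two columns (child, parent)")
  ids <- unique(c(df[[1]], df[[2]]))
  rec <- data.frame(id = ids, name = ids, namespace = namespace,
                    obsolete = FALSE, stringsAsFactors = FALSE)
  edf <- data.frame(child = df[[1]], parent = df[[2]], relation = "is_a",
                    stringsAsFactors = FALSE)
  .new_ontology_graph(rec, edf, namespace, 0L)
}

.new_ontology_graph <- function(records, edges, namespace, n_dropped_edges) {
  g <- igraph::graph_from_data_frame(
    edges[, c("child", "parent"), drop = FALSE],
    directed = TRUE,
    vertices = records[, "id", drop = FALSE]
  )
  if (!igraph::is_dag(g)) {
    comp <- igraph::components(g, mode = "strong")
    bad <- names(comp$membership)[comp$membership == which(comp$csize > 1)[1]]
    if (!length(bad)) bad <- names(which(igraph::which_loop(g)))
    stop("ontology graph contains a cycle among terms: ",
         paste(bad, collapse = ", "))
  }
  structure(
    list(graph = g, records = records, edges = edges,
         namespace = namespace, n_dropped_edges = n_dropped_edges),
    class = "ontology_graph"
  )
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat("ontology_graph:", nrow(x$records), "terms,", nrow(x$edges),
      "edges, namespace:", x$namespace, "\n")
  invisible(x)
}

#' Term identifiers of an ontology graph
#' @param graph An `ontology_graph`.
#' @return Character vector of term ids.
#' @export
term_ids <- function(graph) {
  stopifnot(inherits(graph, "ontology_graph"))
  graph$records$id
}

.check_terms <- function(graph, terms) {
  missing <- setdiff(terms, graph$records$id)
  if (length(missing)) {
    stop("term(s) not in ontology graph: ", paste(missing, collapse = ", "))
  }
}

#' Minimal upward distances from a term to its ancestors
#'
#' Breadth-first edge counts from `term` to every ancestor reachable along
#' child-to-parent edges, including the term itself at distance 0.
#'
#' @param graph An `ontology_graph`.
#' @param term A term id present in the graph.
#' @return Named integer vector of minimal edge counts, one entry per
#'   ancestor (self included at 0).
#' @export
ancestor_distances <- function(graph, term) {
  stopifnot(inherits(graph, "ontology_graph"))
  .check_terms(graph, term)
  d <- igraph::distances(graph$graph, v = term, mode = "out")[1, ]
  d <- d[is.finite(d)]
  storage.mode(d) <- "integer"
  d[order(d, names(d))]
}

#' Common-ancestor distance between two terms
#'
#' The minimum, over every common ancestor `c` of `a` and `b`, of
#' `dist(a, c) + dist(b, c)` in child-to-parent edge counts. Identical
#' terms are at distance 0 (each term is its own ancestor). When the two
#' terms share no ancestor -- possible when namespace restriction leaves
#' multiple roots -- the sentinel `Inf` is returned, so `pair_distance(...)
#' <= t` is always a definite TRUE/FALSE.
#'
#' @param graph An `ontology_graph`.
#' @param a,b Term ids present in the graph.
#' @return A non-negative number of edges, or `Inf` if no common ancestor
#'   exists.
#' @export
pair_distance <- function(graph, a, b) {
  stopifnot(inherits(graph, "ontology_graph"))
  .check_terms(graph, c(a, b))
  if (a == b) return(0)
  d <- igraph::distances(graph$graph, v = c(a, b), mode = "out")
  min(d[1, ] + d[2, ])
}

# Distance rows from a set of terms to every term in the graph; rows are
# the query terms. Used to batch pair_distance over many annotation sets.
.distance_rows <- function(graph, terms) {
  d <- igraph::distances(graph$graph, v = terms, mode = "out")
  rownames(d) <- terms
  d
}

# Minimum total common-ancestor distance over the cross product of two term
# sets, given precomputed distance rows. Returns the distance and the
# lexicographically smallest (source term, target term) pair achieving it.
.pairset_min_distance <- function(drows, s_terms, t_terms) {
  s_terms <- sort(s_terms)
  t_terms <- sort(t_terms)
  ds <- drows[s_terms, , drop = FALSE]
  dt <- drows[t_terms, , drop = FALSE]
  best <- Inf
  best_pair <- c(NA_character_, NA_character_)
  for (i in seq_along(s_terms)) {
    tot <- dt + rep(ds[i, ], each = nrow(dt))
    row_min <- apply(tot, 1, min)
    m <- min(row_min)
    if (m < best) {
      best <- m
      best_pair <- c(s_terms[i], t_terms[which(row_min == m)[1]])
    }
  }
  list(distance = best, pair = best_pair)
}
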