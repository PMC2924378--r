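#' Read an accession alias table
#'
#' Two-column TSV mapping alias accessions to canonical accessions, used to
#' reconcile accession numbering between a minimotif database and the GO
#' annotation source. A header line is optional and detected by name.
#'
#' @param file Path to the TSV.
#' @return A named character vector (`names` = alias, values = canonical)
#'   of class `alias_table`.
#' @export
read_alias_table <- function(file) {
  df <- utils::read.delim(file, header = FALSE, colClasses = "character")
  if (ncol(df) < 2L) stop("alias table must have two columns (alias, canonical)")
  if (nrow(df) && tolower(df[1, 1]) %in% c("alias", "alias_accession")) {
    df <- df[-1, , drop = FALSE]
  }
  alias_table(stats::setNames(df[[2]], df[[1]]))
}

#' Build an alias table from a named vector
#'
#' @param x Named character vector: names are aliases, values canonical
#'   accessions. Accessions are opaque, case-sensitive tokens.
#' @return The vector with class `alias_table`.
#' @export
alias_table <- function(x = character()) {
  stopifnot(is.character(x))
  if (length(x) && is.null(names(x))) stop("alias table entries must be named")
  structure(x, class = "alias_table")
}

#' Resolve an accession through the alias table
#'
#' Unknown accessions pass through unchanged, so resolution is total and
#' idempotent after one hop.
#'
#' @param aliases An `alias_table` (may be empty).
#' @param accession Character vector of accessions.
#' @return Character vector of canonical accessions, same length.
#' @export
resolve_alias <- function(aliases, accession) {
  hit <- match(accession, names(aliases))
  out <- accession
  out[!is.na(hit)] <- unclass(aliases)[hit[!is.na(hit)]]
  out
}

.aspect_for_namespace <- c(biological_process = "P",
                           molecular_function = "F",
                           cellular_component = "C")

#' Parse GO annotations from a GAF 2.x file
#'
#' Reads tab-separated GAF rows (comment lines start with `!`) and keeps
#' those whose aspect column matches the graph's namespace (P for
#' biological_process, F for molecular_function, C for cellular_component).
#' Rows whose qualifier contains `NOT` are skipped, as are rows whose term
#' is absent from the graph (counted in `n_skipped_terms`). Evidence codes
#' are accepted by default; pass codes to `exclude_evidence` to drop them.
#'
#' @param file Path to a GAF file, or a character vector of GAF lines.
#' @param graph The companion `ontology_graph`; its namespace selects the
#'   aspect and its term set bounds the annotations.
#' @param exclude_evidence Character vector of evidence codes to skip.
#' @return An `annotation_set`: list with `terms` (named list mapping
#'   canonical accession to a character vector of term ids), `namespace`,
#'   and `n_skipped_terms`.
#' @export
parse_gaf <- function(file, graph, exclude_evidence = character()) {
  stopifnot(inherits(graph, "ontology_graph"))
  lines <- if (length(file) == 1L && !grepl("\n", file) && file.exists(file)) {
    readLines(file, warn = FALSE)
  } else {
    unlist(strsplit(file, "\n", fixed = TRUE), use.names = FALSE)
  }
  keep <- !startsWith(lines, "!") & nzchar(trimws(lines))
  line_no <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  short <- which(lengths(fields) < 15L)
  if (length(short)) {
    stop("GAF row with fewer than 15 columns at line ", line_no[short[1]])
  }
  aspect <- .aspect_for_namespace[[graph$namespace]] %||%
    stop("graph namespace '", graph$namespace,
         "' has no GAF aspect; parse the ontology with an explicit namespace")
  acc <- vapply(fields, `[[`, "", 2L)
  qualifier <- vapply(fields, `[[`, "", 4L)
  term <- vapply(fields, `[[`, "", 5L)
  evidence <- vapply(fields, `[[`, "", 7L)
  row_aspect <- vapply(fields, `[[`, "", 9L)
  ok <- row_aspect == aspect &
    !grepl("(^|\\|)NOT($|\\|)", qualifier) &
    !(evidence %in% exclude_evidence)
  in_graph <- term %in% graph$records$id
  n_skipped <- sum(ok & !in_graph)
  ok <- ok & in_graph
  terms <- lapply(split(term[ok], acc[ok]), function(x) sort(unique(x)))
  structure(list(terms = terms, namespace = graph$namespace,
                 n_skipped_terms = n_skipped),
            class = "annotation_set")
}

#' Build an annotation set directly from accession/term pairs
#'
#' @param accessions Character vector of accessions (repeated per term).
#' @param terms Character vector of term ids, parallel to `accessions`.
#' @param namespace Namespace label.
#' @return An `annotation_set`.
#' @export
annotation_set <- function(accessions, terms, namespace = "biological_process") {
  stopifnot(length(accessions) == length(terms))
  structure(list(
    terms = lapply(split(terms, accessions), function(x) sort(unique(x))),
    namespace = namespace, n_skipped_terms = 0L
  ), class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat("annotation_set:", length(x$terms), "annotated accessions, namespace:",
      x$namespace, "\n")
  invisible(x)
}

#' Term set of a protein, after alias resolution
#'
#' Looks the accession up through the alias table and returns its annotated
#' term set in the annotation set's namespace. An unannotated protein
#' yields the empty set; downstream filters treat that as not-evaluable and
#' exclude it from totals.
#'
#' @param annotations An `annotation_set`.
#' @param aliases An `alias_table` (may be empty).
#' @param accession A single accession string.
#' @return Character vector of term ids (possibly empty).
#' @export
terms_for <- function(annotations, aliases, accession) {
  stopifnot(inherits(annotations, "annotation_set"))
  canonical <- resolve_alias(aliases, accession)
  annotations$terms[[canonical]] %||% character()
}
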