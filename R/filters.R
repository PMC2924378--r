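#' Configuration for minimotif filtering
#'
#' @param namespace GO namespace of the function filter:
#'   `"biological_process"` (the cellular-function filter) or
#'   `"molecular_function"` (the molecular-function filter). The aliases
#'   `"cellular"` and `"molecular"` are accepted.
#' @param distance_threshold Integer t >= 0: maximum total edge count from
#'   a common ancestor to the two compared terms. t = 0 requires a shared
#'   term.
#' @param frequency_threshold Score bound for the frequency-score filter; a
#'   motif is retained when its expected chance occurrence count is at or
#'   below this (published values 0.02, 0.03, 0.04).
#' @param mode `"function_only"`, `"frequency_only"`, or `"either_or"` (the
#'   combined filter: retained when either component retains).
#' @param invert Logical; the "exclude" mode, swapping retained and
#'   rejected verdicts among evaluable motifs.
#' @param t_range Admissible range for `distance_threshold` (default 0-5,
#'   the published sweep).
#' @return A `filter_config` list.
#' @export
filter_config <- function(namespace = "biological_process",
                          distance_threshold = 0,
                          frequency_threshold = 0.03,
                          mode = c("function_only", "frequency_only", "either_or"),
                          invert = FALSE,
                          t_range = c(0L, 5L)) {
  ns_alias <- c(cellular = "biological_process", molecular = "molecular_function")
  if (namespace %in% names(ns_alias)) namespace <- ns_alias[[namespace]]
  namespace <- match.arg(namespace, c("biological_process",
                                      "molecular_function",
                                      "cellular_component"))
  mode <- match.arg(mode)
  if (distance_threshold < t_range[1] || distance_threshold > t_range[2]) {
    stop("distance_threshold must lie in [", t_range[1], ", ", t_range[2], "]")
  }
  stopifnot(distance_threshold == round(distance_threshold),
            frequency_threshold >= 0, is.logical(invert))
  structure(list(namespace = namespace,
                 distance_threshold = as.integer(distance_threshold),
                 frequency_threshold = frequency_threshold,
                 mode = mode, invert = invert),
            class = "filter_config")
}

.decision <- function(verdict, min_distance = NA_real_, score = NA_real_,
                      component = NA_character_, best_pair = NULL) {
  structure(list(verdict = verdict, min_distance = min_distance,
                 score = score, component = component, best_pair = best_pair),
            class = "filter_decision")
}

#' @export
print.filter_decision <- function(x, ...) {
  cat("filter_decision:", x$verdict,
      if (!is.na(x$min_distance)) paste0("(min_distance = ", x$min_distance, ")"),
      if (!is.na(x$score)) paste0("(score = ", signif(x$score, 4), ")"),
      "\n")
  invisible(x)
}

#' Shared-function filter on two term sets
#'
#' Retains a (source, target) pair when some source term and some target
#' term are joined through a common ancestor within a total of `t` edges;
#' at t = 0 this is exactly a non-empty term-set intersection. A pair where
#' either protein has no annotation is not evaluable and is excluded from
#' evaluation totals downstream.
#'
#' @param source_terms,target_terms Character vectors of term ids (either
#'   may be empty).
#' @param graph The `ontology_graph` for the namespace.
#' @param t Distance threshold (non-negative integer).
#' @return A `filter_decision` with verdict `retained`, `rejected` or
#'   `not_evaluable`; `min_distance` is the minimal cross-product
#'   common-ancestor distance (`Inf` when no pair shares an ancestor), and
#'   `best_pair` the lexicographically smallest (source term, target term)
#'   pair achieving it.
#' @export
function_filter <- function(source_terms, target_terms, graph, t) {
  stopifnot(inherits(graph, "ontology_graph"), t >= 0)
  if (!length(source_terms) || !length(target_terms)) {
    return(.decision("not_evaluable", component = "function"))
  }
  .check_terms(graph, c(source_terms, target_terms))
  drows <- .distance_rows(graph, unique(c(source_terms, target_terms)))
  res <- .pairset_min_distance(drows, unique(source_terms), unique(target_terms))
  .decision(if (res$distance <= t) "retained" else "rejected",
            min_distance = res$distance, component = "function",
            best_pair = res$pair)
}

#' Frequency-score filter on a single minimotif
#'
#' Retains the motif when its expected chance occurrence count in the
#' source protein is at or below the threshold (complex motifs score low).
#' Not evaluable when the source sequence is unavailable.
#'
#' @param motif A list or one-row data frame with `source_accession` and
#'   `motif` (pattern string) entries.
#' @param sequences Named character vector of protein sequences.
#' @param background Named background frequencies.
#' @param threshold Score bound.
#' @param aliases Optional `alias_table` used to look the source up in
#'   `sequences`.
#' @return A `filter_decision` carrying the score.
#' @export
frequency_filter <- function(motif, sequences,
                             background = uniform_background(),
                             threshold = 0.03,
                             aliases = alias_table()) {
  src <- resolve_alias(aliases, motif$source_accession)
  seq <- if (src %in% names(sequences)) sequences[[src]]
         else if (motif$source_accession %in% names(sequences))
           sequences[[motif$source_accession]]
  if (is.null(seq) || is.na(seq) || is.na(motif$motif)) {
    return(.decision("not_evaluable", component = "frequency"))
  }
  s <- frequency_score(motif$motif, nchar(seq), background)
  .decision(if (s <= threshold) "retained" else "rejected",
            score = s, component = "frequency")
}

#' Either-or combination of two filter decisions
#'
#' The combined filter retains a motif when either component retains it; it
#' is not evaluable only when both components are; otherwise it rejects.
#' `component` records which side(s) decided.
#'
#' @param a,b `filter_decision` objects.
#' @return A combined `filter_decision` carrying both diagnostics.
#' @export
combine_either_or <- function(a, b) {
  stopifnot(inherits(a, "filter_decision"), inherits(b, "filter_decision"))
  verdicts <- c(a$verdict, b$verdict)
  verdict <- if (any(verdicts == "retained")) "retained"
  else if (all(verdicts == "not_evaluable")) "not_evaluable"
  else "rejected"
  retainers <- c(a$component, b$component)[verdicts == "retained"]
  .decision(verdict,
            min_distance = if (!is.na(a$min_distance)) a$min_distance else b$min_distance,
            score = if (!is.na(a$score)) a$score else b$score,
            component = if (length(retainers)) paste(retainers, collapse = "+")
                        else "either_or",
            best_pair = a$best_pair %||% b$best_pair)
}

#' Apply a configured filter to a minimotif table
#'
#' Runs the configured filter over every (source, motif, activity, target)
#' row and returns per-motif verdicts plus summary counts. Activity labels
#' are carried through untouched; they play no role in filtering. In
#' `either_or` mode the evaluation universe is restricted to motifs whose
#' function side is evaluable (both proteins annotated); among those, a
#' not-evaluable frequency side leaves the function side to decide. With
#' `invert` (the "exclude" mode) retained and rejected are swapped among
#' evaluable motifs only. Summary totals exclude not-evaluable motifs.
#'
#' @param motifs Data frame with columns `source_accession`, `motif`,
#'   `activity`, `target_accession` (motif/activity may be `NA` for
#'   function-only runs).
#' @param config A `filter_config`.
#' @param resources List with elements `graph` (`ontology_graph`),
#'   `annotations` (`annotation_set`), and optionally `aliases`
#'   (`alias_table`), `sequences` (named character vector) and
#'   `background`.
#' @return List with `decisions` (data frame: row, source_accession,
#'   target_accession, verdict, min_distance, score, component) and
#'   `summary` (list: n_motifs, total evaluable, retained, rejected,
#'   not_evaluable).
#' @export
apply_filter <- function(motifs, config, resources) {
  stopifnot(inherits(config, "filter_config"))
  aliases <- resources$aliases %||% alias_table()
  background <- resources$background %||% uniform_background()
  use_function <- config$mode %in% c("function_only", "either_or")
  use_frequency <- config$mode %in% c("frequency_only", "either_or")

  if (use_function) {
    graph <- resources$graph
    ann <- resources$annotations
    stopifnot(inherits(graph, "ontology_graph"), inherits(ann, "annotation_set"))
    accs <- unique(c(motifs$source_accession, motifs$target_accession))
    term_sets <- lapply(accs, function(a) terms_for(ann, aliases, a))
    names(term_sets) <- accs
    used_terms <- unique(unlist(term_sets, use.names = FALSE))
    if (length(used_terms)) .check_terms(graph, used_terms)
    drows <- if (length(used_terms)) .distance_rows(graph, used_terms)
  }

  n <- nrow(motifs)
  verdict <- character(n)
  min_distance <- rep(NA_real_, n)
  score <- rep(NA_real_, n)
  component <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    fd <- NULL
    if (use_function) {
      st <- term_sets[[motifs$source_accession[i]]]
      tt <- term_sets[[motifs$target_accession[i]]]
      fd <- if (!length(st) || !length(tt)) {
        .decision("not_evaluable", component = "function")
      } else {
        res <- .pairset_min_distance(drows, st, tt)
        .decision(if (res$distance <= config$distance_threshold) "retained"
                  else "rejected",
                  min_distance = res$distance, component = "function")
      }
    }
    qd <- if (use_frequency) {
      frequency_filter(motifs[i, ], resources$sequences %||% character(),
                       background, config$frequency_threshold, aliases)
    }
    d <- if (config$mode == "function_only") fd
    else if (config$mode == "frequency_only") qd
    else if (fd$verdict == "not_evaluable") fd  # function side defines the universe
    else combine_either_or(fd, qd)
    verdict[i] <- d$verdict
    min_distance[i] <- d$min_distance
    score[i] <- d$score
    component[i] <- d$component
  }

  if (config$invert) {
    verdict[verdict == "retained"] <- "swap"
    verdict[verdict == "rejected"] <- "retained"
    verdict[verdict == "swap"] <- "rejected"
  }
  decisions <- data.frame(
    row = seq_len(n),
    source_accession = motifs$source_accession,
    target_accession = motifs$target_accession,
    verdict = verdict, min_distance = min_distance, score = score,
    component = component, stringsAsFactors = FALSE
  )
  list(decisions = decisions,
       summary = list(n_motifs = n,
                      total = sum(verdict != "not_evaluable"),
                      retained = sum(verdict == "retained"),
                      rejected = sum(verdict == "rejected"),
                      not_evaluable = sum(verdict == "not_evaluable")))
}
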