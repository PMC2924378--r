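# Shared fixtures and independent oracles, built in code at test time.

# Six-term toy DAG: A1 -> A, A2 -> A, A -> R, B1 -> B, B -> R
toy_obo <- function(namespace = "biological_process") {
  unlist(lapply(list(c("R", character()), c("A", "R"), c("B", "R"),
                     c("A1", "A"), c("A2", "A"), c("B1", "B")),
                function(x) c("[Term]", paste0("id: ", x[1]),
                              paste0("name: term ", x[1]),
                              paste0("namespace: ", namespace),
                              if (length(x) > 1) paste0("is_a: ", x[2]), "")))
}

toy_graph <- function() parse_obo(toy_obo(), namespace = "biological_process")

# Exhaustive upward search over the raw edge table: minimal distance to every
# ancestor, independent of the igraph-backed implementation.
oracle_ancestors <- function(edges, term) {
  best <- stats::setNames(0, term)
  stack <- list(c(term, 0))
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    node <- top[1]
    d <- as.numeric(top[2])
    for (p in edges$parent[edges$child == node]) {
      nd <- d + 1
      if (is.na(best[p]) || nd < best[p]) {
        best[p] <- nd
        stack[[length(stack) + 1L]] <- c(p, nd)
      }
    }
  }
  best
}

oracle_pair_distance <- function(graph, a, b) {
  da <- oracle_ancestors(graph$edges, a)
  db <- oracle_ancestors(graph$edges, b)
  common <- intersect(names(da), names(db))
  if (!length(common)) Inf else min(da[common] + db[common])
}

# GAF 2.x rows (17 columns) for fixture annotations
gaf_row <- function(acc, term, aspect = "P", qualifier = "enables",
                    evidence = "IEA") {
  paste("SYN", acc, acc, qualifier, term, "SYN_REF:1", evidence, "", aspect,
        "", "", "protein", "taxon:0000", "20260101", "syn", "", "",
        sep = "\t")
}

# Minimal minimotif table
motif_table <- function(source, target, motif = NA_character_,
                        activity = "binds") {
  data.frame(source_accession = source, motif = motif, activity = activity,
             target_accession = target, stringsAsFactors = FALSE)
}

# Decision frame with a given number of retained / rejected / not-evaluable
fake_decisions <- function(retained, rejected, not_evaluable = 0) {
  data.frame(verdict = rep(c("retained", "rejected", "not_evaluable"),
                           c(retained, rejected, not_evaluable)),
             stringsAsFactors = FALSE)
}

# The published cellular-function and molecular-function sweeps
# (distance 0..5: sensitivity %, selectivity %)
cellular_sweep <- function() {
  data.frame(threshold = 0:5,
             sensitivity = c(11, 26, 48, 65, 82, 90),
             selectivity = c(3, 6, 14, 32, 58, 79))
}

molecular_sweep <- function() {
  data.frame(threshold = 0:5,
             sensitivity = c(29, 59, 82, 91, 94, 96),
             selectivity = c(12, 21, 35, 50, 61, 72))
}
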