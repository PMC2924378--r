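#' Configuration for the synthetic benchmark generator
#'
#' Defines a seeded generator of ontology, annotations, aliases, sequences
#' and positive/negative minimotif sets with planted statistical structure.
#' Positives are "verified"-like pairs: with probability
#' `plant_probability` (q) an annotated pair has a target term placed within
#' common-ancestor distance `plant_distance` (d_pos) of a source term, so a
#' function filter at t >= d_pos retains it by construction. Negatives are
#' uniform random ordered pairs kept disjoint from the positives.
#'
#' @param seed RNG seed; every artifact of a run is a pure function of this
#'   configuration.
#' @param n_terms Number of ontology terms (term 1 is the single root).
#' @param max_parents Maximum parents drawn per non-root term (1-2).
#' @param n_proteins Number of proteins.
#' @param terms_per_protein Annotation terms per annotated protein.
#' @param n_pos,n_neg Number of positive and negative minimotif pairs.
#' @param plant_distance Target common-ancestor distance d_pos for planted
#'   positives.
#' @param plant_probability Chance q that an annotated positive pair is
#'   planted within d_pos.
#' @param sequence_length Protein sequence length (residues).
#' @param motif_length Length of generated consensus patterns.
#' @param unannotated_fraction Fraction of proteins deliberately left
#'   without GO annotation (these make pairs not-evaluable, emulating
#'   annotation attrition in real databases).
#' @param alias_fraction Fraction of proteins referred to through an alias
#'   accession in the minimotif tables while the GAF and FASTA use the
#'   canonical accession.
#' @param namespace Namespace label of the generated ontology.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1L, n_terms = 300L, max_parents = 2L,
                             n_proteins = 2000L, terms_per_protein = 3L,
                             n_pos = 1000L, n_neg = 1000L,
                             plant_distance = 1L, plant_probability = 0.6,
                             sequence_length = 400L, motif_length = 4L,
                             unannotated_fraction = 0.15,
                             alias_fraction = 0.1,
                             namespace = "biological_process") {
  cfg <- list(seed = as.integer(seed), n_terms = as.integer(n_terms),
              max_parents = as.integer(max_parents),
              n_proteins = as.integer(n_proteins),
              terms_per_protein = as.integer(terms_per_protein),
              n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
              plant_distance = as.integer(plant_distance),
              plant_probability = plant_probability,
              sequence_length = as.integer(sequence_length),
              motif_length = as.integer(motif_length),
              unannotated_fraction = unannotated_fraction,
              alias_fraction = alias_fraction,
              namespace = namespace)
  stopifnot(cfg$n_terms >= 1, cfg$max_parents >= 1, cfg$max_parents <= 2,
            cfg$n_proteins >= 2, cfg$terms_per_protein >= 1,
            cfg$n_pos >= 1, cfg$n_neg >= 0, cfg$plant_distance >= 0,
            cfg$plant_probability >= 0, cfg$plant_probability <= 1,
            cfg$sequence_length >= 1, cfg$motif_length >= 1,
            cfg$unannotated_fraction >= 0, cfg$unannotated_fraction < 1,
            cfg$alias_fraction >= 0, cfg$alias_fraction <= 1)
  structure(cfg, class = "synthetic_config")
}

#' Generate a random rooted term DAG
#'
#' Term 1 is the root; each later term draws 1 to `max_parents` parents
#' uniformly from the earlier terms, so the graph is acyclic by
#' construction and has a single root.
#'
#' @param config A `synthetic_config`; `config$seed` seeds the RNG.
#' @return An `ontology_graph`.
#' @export
generate_dag <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  .gen_dag(config)
}

.gen_dag <- function(config) {
  n <- config$n_terms
  ids <- sprintf("GO:%07d", seq_len(n))
  child <- character()
  parent <- character()
  if (n > 1) {
    for (i in 2:n) {
      k <- sample.int(config$max_parents, 1L)
      p <- if (i == 2) 1L else sample.int(i - 1L, min(k, i - 1L))
      child <- c(child, rep(ids[i], length(p)))
      parent <- c(parent, ids[p])
    }
  }
  rec <- data.frame(id = ids, name = paste("synthetic term", seq_len(n)),
                    namespace = config$namespace, obsolete = FALSE,
                    stringsAsFactors = FALSE)
  edf <- data.frame(child = child, parent = parent,
                    relation = rep("is_a", length(child)),
                    stringsAsFactors = FALSE)
  .new_ontology_graph(rec, edf, config$namespace, 0L)
}

#' Generate annotated positive and negative minimotif pairs
#'
#' Annotates proteins with random term sets, then samples positive pairs
#' (targets drawn without replacement so plantings never interfere) and
#' plants, with probability q, a target term within `plant_distance` of a
#' source term. Negatives are uniform random ordered pairs resampled until
#' disjoint from the positives (capped at 100x the requested count). Each
#' pair carries a random fixed-letter consensus pattern; positives record a
#' `planted` truth flag.
#'
#' @param config A `synthetic_config`; `config$seed` seeds the RNG.
#' @param graph An `ontology_graph` from [generate_dag()].
#' @return A `synthetic_dataset` (without sequences; see
#'   [generate_sequences_with_motifs()]).
#' @export
generate_pairs <- function(config, graph) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  .gen_pairs(config, graph)
}

.gen_pairs <- function(config, graph) {
  n_prot <- config$n_proteins
  acc <- sprintf("PROT%05d", seq_len(n_prot))
  annotated <- stats::runif(n_prot) >= config$unannotated_fraction
  ids <- term_ids(graph)
  term_sets <- vector("list", n_prot)
  names(term_sets) <- acc
  for (i in which(annotated)) {
    term_sets[[i]] <- sample(ids, min(config$terms_per_protein, length(ids)))
  }

  # full ancestor-distance matrix: rows/cols = all terms, upward distances
  dmat <- .distance_rows(graph, ids)
  near_cache <- new.env(parent = emptyenv())
  near_terms <- function(s, d) {
    hit <- get0(s, envir = near_cache)
    if (!is.null(hit)) return(hit)
    pd <- apply(dmat, 1, function(r) min(r + dmat[s, ]))
    out <- ids[pd <= d]
    assign(s, out, envir = near_cache)
    out
  }

  if (config$n_pos > n_prot - 1L) {
    stop("pair space too small: n_pos exceeds available target proteins")
  }
  src <- sample(acc, config$n_pos, replace = TRUE)
  tgt <- sample(acc, config$n_pos, replace = FALSE)
  clash <- which(src == tgt)
  for (i in clash) {  # targets are distinct, so swapping two fixes a clash
    j <- if (i == 1L) 2L else 1L
    tmp <- tgt[i]; tgt[i] <- tgt[j]; tgt[j] <- tmp
  }
  planted <- logical(config$n_pos)
  for (i in seq_len(config$n_pos)) {
    s_terms <- term_sets[[src[i]]]
    t_terms <- term_sets[[tgt[i]]]
    if (is.null(s_terms) || is.null(t_terms)) next
    if (stats::runif(1) < config$plant_probability) {
      s <- sample(s_terms, 1L)
      u <- sample(near_terms(s, config$plant_distance), 1L)
      # plant by adding, never removing: earlier plants can then never be
      # disturbed when a source protein later serves as another pair's target
      term_sets[[tgt[i]]] <- unique(c(t_terms, u))
      planted[i] <- TRUE
    }
  }

  pos_key <- paste(src, tgt, sep = "\r")
  neg_src <- character(0)
  neg_tgt <- character(0)
  draws <- 0L
  max_draws <- 100L * config$n_neg
  while (length(neg_src) < config$n_neg) {
    need <- config$n_neg - length(neg_src)
    if (draws >= max_draws) {
      stop("pair space too small to sample disjoint negatives")
    }
    batch <- min(max(2L * need, 100L), max_draws - draws)
    draws <- draws + batch
    s <- sample(acc, batch, replace = TRUE)
    t <- sample(acc, batch, replace = TRUE)
    key <- paste(s, t, sep = "\r")
    ok <- s != t & !(key %in% pos_key) & !duplicated(key) &
      !(key %in% paste(neg_src, neg_tgt, sep = "\r"))
    take <- seq_len(min(need, sum(ok)))
    neg_src <- c(neg_src, s[ok][take])
    neg_tgt <- c(neg_tgt, t[ok][take])
  }

  rand_pattern <- function(n) {
    vapply(seq_len(n), function(i) {
      paste(sample(AA20, config$motif_length, replace = TRUE), collapse = "")
    }, "")
  }
  activities <- c("binds", "modifies", "traffics")

  with_alias <- acc[stats::runif(n_prot) < config$alias_fraction]
  aliases <- alias_table(stats::setNames(with_alias, paste0("ALIAS_", with_alias)))
  motif_name <- function(a) {
    ifelse(a %in% with_alias, paste0("ALIAS_", a), a)
  }

  positives <- data.frame(
    source_accession = motif_name(src), motif = rand_pattern(config$n_pos),
    activity = sample(activities, config$n_pos, replace = TRUE),
    target_accession = motif_name(tgt), stringsAsFactors = FALSE
  )
  negatives <- data.frame(
    source_accession = motif_name(neg_src),
    motif = rand_pattern(length(neg_src)),
    activity = sample(activities, length(neg_src), replace = TRUE),
    target_accession = motif_name(neg_tgt), stringsAsFactors = FALSE
  )

  ann_acc <- rep(acc, lengths(term_sets))
  ann_terms <- unlist(term_sets, use.names = FALSE)
  structure(list(
    config = config, graph = graph,
    annotations = annotation_set(ann_acc, ann_terms, config$namespace),
    aliases = aliases, sequences = NULL,
    positives = positives, negatives = negatives,
    truth = planted
  ), class = "synthetic_dataset")
}

#' Generate sequences and implant the positive motifs
#'
#' Draws uniform-random amino-acid sequences of `sequence_length` for every
#' protein and implants each positive's consensus pattern at a recorded
#' 1-based position in its source sequence.
#'
#' @param config A `synthetic_config`; `config$seed` seeds the RNG.
#' @param dataset A `synthetic_dataset` from [generate_pairs()].
#' @return The dataset with `sequences` (named character vector, canonical
#'   accessions) and `implants` (data frame: row, accession, start) filled
#'   in.
#' @export
generate_sequences_with_motifs <- function(config, dataset) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(dataset, "synthetic_dataset"))
  set.seed(config$seed)
  .gen_sequences(config, dataset)
}

.gen_sequences <- function(config, dataset) {
  if (config$motif_length > config$sequence_length) {
    stop("motif_length exceeds sequence_length")
  }
  acc <- sprintf("PROT%05d", seq_len(config$n_proteins))
  L <- config$sequence_length
  seqs <- vapply(acc, function(a) {
    paste(sample(AA20, L, replace = TRUE), collapse = "")
  }, "")
  k <- config$motif_length
  n_pos <- nrow(dataset$positives)
  src_can <- resolve_alias(dataset$aliases, dataset$positives$source_accession)
  starts <- integer(n_pos)
  used <- new.env(parent = emptyenv())  # per-protein implant intervals
  for (i in seq_len(n_pos)) {
    prior <- get0(src_can[i], envir = used) %||% integer()
    for (try in 1:100) {  # keep implants on one protein from overwriting each other
      st <- sample.int(L - k + 1L, 1L)
      if (!any(abs(prior - st) < k)) break
    }
    starts[i] <- st
    assign(src_can[i], c(prior, st), envir = used)
    substr(seqs[[src_can[i]]], st, st + k - 1L) <- dataset$positives$motif[i]
  }
  dataset$sequences <- seqs
  dataset$implants <- data.frame(row = seq_len(n_pos), accession = src_can,
                                 start = starts, stringsAsFactors = FALSE)
  dataset
}

#' Generate a complete synthetic dataset
#'
#' Runs [generate_dag()], [generate_pairs()] and
#' [generate_sequences_with_motifs()] under one seeding of the RNG, so the
#' whole dataset is a pure function of the configuration.
#'
#' @param config A `synthetic_config`.
#' @return A `synthetic_dataset` with graph, annotations, aliases,
#'   sequences, positives, negatives, truth flags and implant positions.
#' @export
generate_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  g <- .gen_dag(config)
  ds <- .gen_pairs(config, g)
  .gen_sequences(config, ds)
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("synthetic_dataset:", nrow(x$graph$records), "terms,",
      x$config$n_proteins, "proteins,", nrow(x$positives), "positives,",
      nrow(x$negatives), "negatives (seed", x$config$seed, ")\n")
  invisible(x)
}

#' Resource list of a synthetic dataset
#'
#' Convenience accessor shaping a dataset for [apply_filter()] and
#' [threshold_sweep()].
#'
#' @param dataset A `synthetic_dataset`.
#' @return List with graph, annotations, aliases, sequences, background.
#' @export
dataset_resources <- function(dataset) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  list(graph = dataset$graph, annotations = dataset$annotations,
       aliases = dataset$aliases, sequences = dataset$sequences,
       background = uniform_background())
}

#' Write a synthetic dataset in the pipeline's on-disk formats
#'
#' Writes `ontology.obo`, `annotations.gaf`, `aliases.tsv`,
#' `sequences.fasta`, `positives.tsv`, `negatives.tsv` and `manifest.json`
#' (echoing the full configuration) so that end-to-end runs exercise the
#' same parsers as real data.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_obo(dataset$graph, file.path(dir, "ontology.obo"))
  write_gaf(dataset$annotations, file.path(dir, "annotations.gaf"))
  al <- dataset$aliases
  utils::write.table(
    data.frame(alias = names(al), canonical = unclass(al)),
    file.path(dir, "aliases.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  if (!is.null(dataset$sequences)) {
    write_fasta(dataset$sequences, file.path(dir, "sequences.fasta"))
  }
  utils::write.table(dataset$positives, file.path(dir, "positives.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$negatives, file.path(dir, "negatives.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(unclass(dataset$config),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Write an ontology graph as OBO
#'
#' @param graph An `ontology_graph`.
#' @param file Output path.
#' @export
write_obo <- function(graph, file) {
  stopifnot(inherits(graph, "ontology_graph"))
  parents <- split(graph$edges$parent, graph$edges$child)
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in seq_len(nrow(graph$records))) {
    r <- graph$records[i, ]
    writeLines(c("[Term]", paste0("id: ", r$id), paste0("name: ", r$name),
                 paste0("namespace: ", r$namespace),
                 paste0("is_a: ", parents[[r$id]] %||% character()), ""), con)
  }
  invisible(file)
}

#' Write an annotation set as GAF 2.2
#'
#' @param annotations An `annotation_set`.
#' @param file Output path.
#' @export
write_gaf <- function(annotations, file) {
  stopifnot(inherits(annotations, "annotation_set"))
  aspect <- .aspect_for_namespace[[annotations$namespace]]
  acc <- rep(names(annotations$terms), lengths(annotations$terms))
  term <- unlist(annotations$terms, use.names = FALSE)
  rows <- paste("SYN", acc, acc, "enables", term, "SYN_REF:0000001", "IEA",
                "", aspect, "", "", "protein", "taxon:0000", "20260101",
                "slimfilter", "", "", sep = "\t")
  writeLines(c("!gaf-version: 2.2", rows), file)
  invisible(file)
}
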