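test_that("function_filter retains within t, rejects beyond, skips unannotated", {
  g <- toy_graph()
  expect_equal(function_filter("A1", "A2", g, t = 1)$verdict, "rejected")
  d2 <- function_filter("A1", "A2", g, t = 2)
  expect_equal(d2$verdict, "retained")
  expect_equal(d2$min_distance, 2)

  # shared term is a common ancestor at total distance 0
  expect_equal(function_filter(c("A1", "B1"), c("B1"), g, t = 0)$verdict,
               "retained")
  expect_equal(function_filter("A1", character(), g, t = 5)$verdict,
               "not_evaluable")
  expect_equal(function_filter(character(), "A1", g, t = 5)$verdict,
               "not_evaluable")
  # sentinel distance counts as failure at any threshold
  g2 <- parse_obo(c("[Term]", "id: R1", "[Term]", "id: R2"))
  expect_equal(function_filter("R1", "R2", g2, t = 100)$verdict, "rejected")
})

test_that("ties in the minimum report the lexicographically smallest pair", {
  g <- toy_graph()
  # both (A1,A2) and (A2,A1) orderings reach distance 2 via A
  fd <- function_filter(c("A2", "A1"), c("A2", "A1"), g, t = 5)
  expect_equal(fd$min_distance, 0)      # shared terms
  expect_equal(fd$best_pair, c("A1", "A1"))
  fd2 <- function_filter(c("B1", "A2"), c("A1"), g, t = 5)
  expect_equal(fd2$best_pair, c("A2", "A1"))
})

test_that("frequency_filter thresholds the expected-occurrence score", {
  seqs <- c(SRC = paste(rep("A", 11), collapse = ""))
  m <- list(source_accession = "SRC", motif = "AC")  # score 0.025
  expect_equal(frequency_filter(m, seqs, threshold = 0.02)$verdict, "rejected")
  d <- frequency_filter(m, seqs, threshold = 0.03)
  expect_equal(d$verdict, "retained")
  expect_equal(d$score, 0.025)

  wild <- list(source_accession = "SRC", motif = "xx")
  expect_equal(frequency_filter(wild, seqs, threshold = 0.04)$verdict,
               "rejected")  # score >= 1
  none <- list(source_accession = "GONE", motif = "AC")
  expect_equal(frequency_filter(none, seqs, threshold = 0.04)$verdict,
               "not_evaluable")
})

test_that("either-or combination retains when either side retains", {
  r <- slimfilter:::.decision("retained", component = "function")
  j <- slimfilter:::.decision("rejected", component = "function")
  ne <- slimfilter:::.decision("not_evaluable", component = "frequency")
  expect_equal(combine_either_or(r, j)$verdict, "retained")
  expect_equal(combine_either_or(j, r)$verdict, "retained")
  expect_equal(combine_either_or(j, j)$verdict, "rejected")
  expect_equal(combine_either_or(ne, ne)$verdict, "not_evaluable")
  expect_equal(combine_either_or(ne, j)$verdict, "rejected")
  expect_equal(combine_either_or(ne, r)$verdict, "retained")
  expect_equal(combine_either_or(r, r)$component, "function+function")
})

make_toy_resources <- function() {
  g <- toy_graph()
  ann <- annotation_set(
    c("P1", "P2", "P3", "P4"),
    c("A1", "A2", "B1", "A1")
  )
  seqs <- c(P1 = paste(rep("A", 11), collapse = ""),
            P2 = paste(rep("C", 11), collapse = ""))
  list(graph = g, annotations = ann, aliases = alias_table(),
       sequences = seqs, background = uniform_background())
}

test_that("apply_filter counts evaluable motifs and honors invert", {
  res <- make_toy_resources()
  # P1{A1} vs P4{A1}: shared; P1 vs P2: distance 2; P1 vs UNANN: not evaluable
  tab <- motif_table(c("P1", "P1", "P1"), c("P4", "P2", "UNANN"))
  cfg <- filter_config(distance_threshold = 0)
  out <- apply_filter(tab, cfg, res)
  expect_equal(out$summary$total, 2)
  expect_equal(out$summary$retained, 1)
  expect_equal(out$summary$not_evaluable, 1)
  expect_equal(out$decisions$verdict, c("retained", "rejected", "not_evaluable"))

  inv <- apply_filter(tab, filter_config(distance_threshold = 0, invert = TRUE), res)
  expect_equal(inv$summary$total, 2)
  expect_equal(inv$summary$retained, 1)  # the previously rejected one
  expect_equal(inv$decisions$verdict, c("rejected", "retained", "not_evaluable"))
  # involution: inverting twice restores the original verdicts
  v <- inv$decisions$verdict
  v[v == "retained"] <- "swap"; v[v == "rejected"] <- "retained"; v[v == "swap"] <- "rejected"
  expect_equal(v, out$decisions$verdict)
  # retained + inverted-retained partition the evaluable motifs
  expect_equal(out$summary$retained + inv$summary$retained, out$summary$total)
})

test_that("t=0 agrees with a set-intersection oracle on random term sets", {
  ds <- generate_dataset(synthetic_config(seed = 9, n_terms = 60,
                                          n_proteins = 80, n_pos = 10,
                                          n_neg = 10))
  ids <- term_ids(ds$graph)
  set.seed(99)
  for (i in 1:50) {
    s <- sample(ids, sample(1:4, 1))
    t <- sample(ids, sample(1:4, 1))
    fd <- function_filter(s, t, ds$graph, t = 0)
    expect_equal(fd$verdict == "retained", length(intersect(s, t)) > 0)
  }
})

test_that("retained sets are nested in t and either-or dominates components", {
  ds <- generate_dataset(synthetic_config(seed = 21, n_terms = 80,
                                          n_proteins = 120, n_pos = 60,
                                          n_neg = 60))
  res <- dataset_resources(ds)
  retained_at <- function(mode, t, q = 0.03) {
    cfg <- filter_config(distance_threshold = t, frequency_threshold = q,
                         mode = mode)
    d <- apply_filter(ds$positives, cfg, res)$decisions
    d$row[d$verdict == "retained"]
  }
  prev <- integer()
  for (t in 0:5) {
    cur <- retained_at("function_only", t)
    expect_true(all(prev %in% cur))
    prev <- cur
  }
  # frequency threshold monotonicity, over patterns with spread-out scores
  varied <- motif_table(ds$positives$source_accession[1:5],
                        ds$positives$target_accession[1:5],
                        motif = c("A", "AC", "ACD", "ACDE", "[ST]PC"))
  freq_retained <- function(q) {
    d <- apply_filter(varied, filter_config(mode = "frequency_only",
                                            frequency_threshold = q),
                      res)$decisions
    d$row[d$verdict == "retained"]
  }
  q_sets <- lapply(c(0.001, 0.01, 0.1, 2, 30), freq_retained)
  for (i in 1:4) expect_true(all(q_sets[[i]] %in% q_sets[[i + 1]]))
  expect_gt(length(q_sets[[5]]), length(q_sets[[1]]))
  # either-or retains a superset of each evaluable component
  fun1 <- retained_at("function_only", 1)
  frq <- retained_at("frequency_only", 1)
  both <- retained_at("either_or", 1)
  expect_true(all(fun1 %in% both))
  d <- apply_filter(ds$positives, filter_config(distance_threshold = 1,
                                                mode = "function_only"),
                    res)$decisions
  evaluable <- d$row[d$verdict != "not_evaluable"]
  expect_true(all(intersect(frq, evaluable) %in% both))
})

test_that("either-or universe is bounded by the function side", {
  res <- make_toy_resources()
  # source annotated+sequenced, target unannotated: function side rules it out
  tab <- motif_table("P1", "UNANN", motif = "AC")
  out <- apply_filter(tab, filter_config(mode = "either_or",
                                         frequency_threshold = 1), res)
  expect_equal(out$decisions$verdict, "not_evaluable")
  # evaluable function side + missing sequence: function side decides alone
  tab2 <- motif_table("P3", "P1", motif = "AC")  # P3 has no sequence
  out2 <- apply_filter(tab2, filter_config(mode = "either_or",
                                           distance_threshold = 5), res)
  expect_equal(out2$decisions$verdict, "retained")
})
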