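test_that("evaluate_filter computes sensitivity, selectivity and DR", {
  ev <- evaluate_filter(fake_decisions(5, 5), fake_decisions(2, 8))
  expect_equal(ev$sensitivity, 50)
  expect_equal(ev$selectivity, 20)
  expect_equal(ev$dr, 2.5)

  # not-evaluable motifs leave the denominators
  ev2 <- evaluate_filter(fake_decisions(5, 5, 10), fake_decisions(2, 8, 3))
  expect_equal(ev2$n_pos_evaluable, 10)
  expect_equal(ev2$sensitivity, 50)

  # all negatives rejected: DR undefined
  expect_true(is.na(evaluate_filter(fake_decisions(5, 5),
                                    fake_decisions(0, 10))$dr))
  expect_error(evaluate_filter(fake_decisions(0, 0, 5), fake_decisions(1, 1)),
               "positive")
  expect_error(evaluate_filter(fake_decisions(1, 1), fake_decisions(0, 0, 5)),
               "negative")
})

test_that("threshold_sweep is monotone per threshold and supports grids", {
  ds <- generate_dataset(synthetic_config(seed = 13, n_terms = 80,
                                          n_proteins = 150, n_pos = 80,
                                          n_neg = 80))
  res <- dataset_resources(ds)
  cfg <- filter_config()
  sw <- threshold_sweep(ds$positives, ds$negatives, res, cfg, 0:2)
  expect_equal(nrow(sw), 3)
  expect_false(is.unsorted(sw$sensitivity))
  expect_false(is.unsorted(sw$selectivity))

  one <- threshold_sweep(ds$positives, ds$negatives, res, cfg, 1)
  cfg1 <- filter_config(distance_threshold = 1)
  ev <- evaluate_filter(apply_filter(ds$positives, cfg1, res),
                        apply_filter(ds$negatives, cfg1, res))
  expect_equal(one$sensitivity, ev$sensitivity)
  expect_equal(one$dr, ev$dr)

  grid <- threshold_sweep(ds$positives, ds$negatives, res,
                          filter_config(mode = "either_or"),
                          thresholds = 0:2,
                          freq_thresholds = c(0.02, 0.03, 0.04))
  expect_equal(nrow(grid), 9)
  expect_error(threshold_sweep(ds$positives, ds$negatives, res, cfg,
                               c(2, 1, 0)),
               "strictly increasing")
})

test_that("roc_from_sweep anchors, sorts and integrates by trapezoid", {
  empty <- roc_from_sweep(data.frame(sensitivity = numeric(),
                                     selectivity = numeric())[0, ])
  expect_equal(empty$auc, 0.5)  # anchors only: the diagonal

  perfect <- roc_from_sweep(data.frame(sensitivity = 100, selectivity = 0))
  expect_equal(perfect$auc, 1.0)

  diag4 <- roc_from_sweep(data.frame(sensitivity = c(25, 50, 75),
                                     selectivity = c(25, 50, 75)))
  expect_equal(diag4$auc, 0.5)

  r <- roc_from_sweep(cellular_sweep())
  expect_true(all(diff(r$points$fpr) >= 0))
  expect_equal(r$points[1, ], data.frame(fpr = 0, tpr = 0))
  expect_gte(r$auc, 0); expect_lte(r$auc, 1)
  # anchors appear exactly once even if a sweep point repeats them
  rep_anchor <- roc_from_sweep(data.frame(sensitivity = c(0, 100),
                                          selectivity = c(0, 100)))
  expect_equal(nrow(rep_anchor$points), 2)
})

test_that("rank test matches the Mann-Whitney/AUC identity on tie-free scores", {
  set.seed(31)
  pos <- rnorm(25, mean = 1)
  neg <- rnorm(30)
  u <- unname(stats::wilcox.test(pos, neg)$statistic)
  auc <- slimfilter:::.mw_auc(pos, neg)
  expect_equal(auc, u / (25 * 30))
  # and the same AUC arises from a trapezoidal ROC over all score thresholds
  cuts <- sort(unique(c(pos, neg)), decreasing = TRUE)
  sweep_df <- data.frame(sensitivity = 100 * vapply(cuts, function(c) mean(pos >= c), 0),
                         selectivity = 100 * vapply(cuts, function(c) mean(neg >= c), 0))
  expect_equal(roc_from_sweep(sweep_df)$auc, auc)
})

test_that("significance behaves at the exchangeable and separated extremes", {
  x <- c(1, 2, 3, 4, 5)
  p_same <- significance(x, x, method = "rank_test")$p_value
  expect_gt(p_same, 0.4); expect_lt(p_same, 0.65)

  pos <- 101:120; neg <- 1:20
  p_rank <- significance(pos, neg, method = "rank_test")$p_value
  expect_lt(p_rank, 1e-4)
  p_perm <- significance(pos, neg, method = "permutation",
                         n_permutations = 999, seed = 4)
  expect_equal(p_perm$p_value, 1 / 1000)  # no permutation can beat AUC 1
  expect_equal(p_perm$auc, 1)
  expect_error(significance(pos, neg, method = "permutation"), "seed")
  expect_error(significance(pos, neg, method = "bootstrap"))
})

test_that("permutation p matches exhaustive label enumeration at n=4+4", {
  pos <- c(9, 7, 6, 2)
  neg <- c(5, 4, 3, 1)
  obs <- slimfilter:::.mw_auc(pos, neg)
  all_scores <- c(pos, neg)
  combos <- utils::combn(8, 4)
  aucs <- apply(combos, 2, function(idx)
    slimfilter:::.mw_auc(all_scores[idx], all_scores[-idx]))
  p_exact <- mean(aucs >= obs)
  p_mc <- significance(pos, neg, method = "permutation",
                       n_permutations = 4999, seed = 2)$p_value
  se <- sqrt(p_exact * (1 - p_exact) / 4999)
  expect_lt(abs(p_mc - p_exact), 3 * se + 1 / 5000)
})

test_that("seeded permutation p-values are roughly uniform under the null", {
  set.seed(77)
  ps <- vapply(1:40, function(i) {
    x <- rnorm(12); y <- rnorm(12)
    significance(x, y, method = "permutation", n_permutations = 199,
                 seed = i)$p_value
  }, 0)
  # permutation p-values are discrete, so ties are expected; the KS bound
  # is still a usable sanity check at this alpha
  ks <- suppressWarnings(stats::ks.test(ps, "punif")$p.value)
  expect_gt(ks, 0.001)
})

test_that("disjointness_check counts shared ordered pairs", {
  pos <- motif_table(c("A", "B"), c("X", "Y"))
  neg <- motif_table(c("A", "C"), c("X", "Z"))
  expect_equal(disjointness_check(pos, neg), 1)
  expect_equal(disjointness_check(pos, motif_table("Q", "R")), 0)
  # reversed orientation is a different ordered pair
  expect_equal(disjointness_check(pos, motif_table("X", "A")), 0)
})
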