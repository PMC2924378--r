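.as_decisions <- function(x) {
  if (is.list(x) && !is.null(x$decisions)) x <- x$decisions
  stopifnot(is.data.frame(x), "verdict" %in% names(x))
  x
}

#' Sensitivity, selectivity and discrimination ratio of a filter run
#'
#' Sensitivity is the percentage of evaluable positive (verified) minimotifs
#' the filter retains; selectivity is the percentage of evaluable negative
#' (random-pair) minimotifs it retains — lower is better. Their ratio is the
#' discrimination ratio (DR); a DR above 1 means the filter preferentially
#' keeps verified motifs. Not-evaluable motifs (no GO annotation on source
#' or target) are excluded from both denominators.
#'
#' @param decisions_pos,decisions_neg Decision data frames (or
#'   `apply_filter()` results) for the positive and negative sets.
#' @return An `evaluation_summary`: list with `n_pos_evaluable`,
#'   `n_neg_evaluable`, `sensitivity` and `selectivity` (percent), and `dr`
#'   (`NA` when selectivity is 0).
#' @export
evaluate_filter <- function(decisions_pos, decisions_neg) {
  pos <- .as_decisions(decisions_pos)
  neg <- .as_decisions(decisions_neg)
  n_pos <- sum(pos$verdict != "not_evaluable")
  n_neg <- sum(neg$verdict != "not_evaluable")
  if (n_pos == 0) stop("no evaluable positive minimotifs")
  if (n_neg == 0) stop("no evaluable negative minimotifs")
  sens <- 100 * sum(pos$verdict == "retained") / n_pos
  sel <- 100 * sum(neg$verdict == "retained") / n_neg
  structure(list(n_pos_evaluable = n_pos, n_neg_evaluable = n_neg,
                 sensitivity = sens, selectivity = sel,
                 dr = if (sel > 0) sens / sel else NA_real_),
            class = "evaluation_summary")
}

#' @export
print.evaluation_summary <- function(x, ...) {
  cat(sprintf("sensitivity %.0f%% (n=%d)  selectivity %.0f%% (n=%d)  DR %s\n",
              x$sensitivity, x$n_pos_evaluable, x$selectivity,
              x$n_neg_evaluable,
              if (is.na(x$dr)) "undefined" else sprintf("%.1f", x$dr)))
  invisible(x)
}

#' Sweep a filter over thresholds
#'
#' Applies the filter family at each threshold and evaluates it against the
#' positive and negative sets. For a distance sweep, `thresholds` is a
#' strictly increasing vector of t values and the resulting sensitivity and
#' selectivity columns must be non-decreasing (a violation indicates a
#' filter bug and raises an error). For a combined-filter grid, pass
#' `freq_thresholds` as well: one row per (distance, frequency-threshold)
#' combination, with no monotonicity assertion across the grid.
#'
#' @param positives,negatives Minimotif data frames.
#' @param resources Resource list as for [apply_filter()].
#' @param config Template `filter_config`; its thresholds are overridden.
#' @param thresholds Strictly increasing distance thresholds.
#' @param freq_thresholds Optional frequency-score thresholds (grid mode).
#' @return Data frame with one row per threshold (or grid cell): threshold,
#'   (freq_threshold,) n_pos, n_neg, sensitivity, selectivity, dr.
#' @export
threshold_sweep <- function(positives, negatives, resources, config,
                            thresholds = 0:5, freq_thresholds = NULL) {
  stopifnot(inherits(config, "filter_config"))
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be strictly increasing")
  }
  grid <- if (is.null(freq_thresholds)) {
    data.frame(threshold = thresholds, freq_threshold = config$frequency_threshold)
  } else {
    expand.grid(freq_threshold = freq_thresholds, threshold = thresholds)[, 2:1]
  }
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cfg <- config
    cfg$distance_threshold <- as.integer(grid$threshold[i])
    cfg$frequency_threshold <- grid$freq_threshold[i]
    ev <- evaluate_filter(apply_filter(positives, cfg, resources),
                          apply_filter(negatives, cfg, resources))
    data.frame(threshold = grid$threshold[i],
               freq_threshold = grid$freq_threshold[i],
               n_pos = ev$n_pos_evaluable, n_neg = ev$n_neg_evaluable,
               sensitivity = ev$sensitivity, selectivity = ev$selectivity,
               dr = ev$dr)
  })
  out <- do.call(rbind, rows)
  if (is.null(freq_thresholds)) {
    out$freq_threshold <- NULL
    if (is.unsorted(out$sensitivity) || is.unsorted(out$selectivity)) {
      stop("internal consistency error: retention must be non-decreasing in t")
    }
  }
  out
}

#' ROC curve from a threshold sweep
#'
#' Builds the ROC as the swept (selectivity/100, sensitivity/100) points —
#' selectivity here is the false-positive rate — plus the (0,0) and (1,1)
#' anchors, deduplicated and sorted by FPR (ties by TPR), and integrates by
#' the trapezoidal rule.
#'
#' @param summaries Data frame with `sensitivity` and `selectivity` percent
#'   columns (as from [threshold_sweep()]), or a list of
#'   `evaluation_summary` objects.
#' @param parameter Name of the swept parameter, recorded on the curve.
#' @return A `roc_curve`: list with `points` (data frame fpr/tpr), `auc`,
#'   `parameter`.
#' @export
roc_from_sweep <- function(summaries, parameter = "distance") {
  if (!is.data.frame(summaries)) {
    summaries <- do.call(rbind, lapply(summaries, function(s) {
      data.frame(sensitivity = s$sensitivity, selectivity = s$selectivity)
    }))
  }
  pts <- data.frame(fpr = summaries$selectivity / 100,
                    tpr = summaries$sensitivity / 100)
  pts <- rbind(data.frame(fpr = 0, tpr = 0), pts, data.frame(fpr = 1, tpr = 1))
  pts <- unique(pts[order(pts$fpr, pts$tpr), , drop = FALSE])
  rownames(pts) <- NULL
  auc <- sum(diff(pts$fpr) * (pts$tpr[-1] + pts$tpr[-nrow(pts)]) / 2)
  structure(list(points = pts, auc = auc, parameter = parameter),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat("roc_curve over", x$parameter, ":", nrow(x$points),
      sprintf("points, AUC %.3f (%.1f at one decimal)\n", x$auc, x$auc))
  invisible(x)
}

#' Plot a ROC curve
#' @param x A `roc_curve`.
#' @param ... Passed to [plot()].
#' @export
plot.roc_curve <- function(x, ...) {
  plot(x$points$fpr, x$points$tpr, type = "b",
       xlab = "False-positive rate (selectivity)",
       ylab = "True-positive rate (sensitivity)",
       main = sprintf("AUC = %.2f", x$auc), xlim = 0:1, ylim = 0:1, ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(x)
}

#' Significance of the positive/negative score separation
#'
#' Scores are per-pair filter diagnostics oriented so that higher means
#' more motif-like: for function filters, the negated minimal
#' common-ancestor distance (the no-ancestor sentinel ranks worst); for the
#' frequency filter, the negated frequency score. `rank_test` is the
#' one-sided Wilcoxon rank-sum test (normal approximation with tie
#' correction) of the null that positives do not score higher than
#' negatives. `permutation` shuffles the pos/neg labels `n_permutations`
#' times (seeded) and reports the fraction of permutations whose
#' Mann-Whitney AUC reaches the observed one, with +1/(n+1) smoothing.
#'
#' @param pos_scores,neg_scores Numeric score vectors (may contain `-Inf`
#'   for sentinel distances).
#' @param method `"rank_test"` or `"permutation"`.
#' @param n_permutations Number of label permutations.
#' @param seed RNG seed, required for `"permutation"`.
#' @return A `significance_result`: list with `p_value`, `method`, `auc`,
#'   and for permutation also `n_permutations` and `seed`.
#' @export
significance <- function(pos_scores, neg_scores,
                         method = c("rank_test", "permutation"),
                         n_permutations = 999, seed = NULL) {
  method <- match.arg(method)
  stopifnot(length(pos_scores) > 0, length(neg_scores) > 0)
  auc_obs <- .mw_auc(pos_scores, neg_scores)
  if (method == "rank_test") {
    p <- stats::wilcox.test(pos_scores, neg_scores, alternative = "greater",
                            exact = FALSE, correct = TRUE)$p.value
    res <- list(p_value = p, method = "rank_test", auc = auc_obs)
  } else {
    if (is.null(seed)) stop("permutation method requires a seed")
    set.seed(seed)
    all_scores <- c(pos_scores, neg_scores)
    n1 <- length(pos_scores)
    hits <- 0L
    for (i in seq_len(n_permutations)) {
      idx <- sample.int(length(all_scores), n1)
      if (.mw_auc(all_scores[idx], all_scores[-idx]) >= auc_obs) hits <- hits + 1L
    }
    res <- list(p_value = (hits + 1) / (n_permutations + 1),
                method = "permutation", auc = auc_obs,
                n_permutations = n_permutations, seed = seed)
  }
  structure(res, class = "significance_result")
}

# Mann-Whitney AUC: P(pos > neg) + 0.5 P(pos == neg), rank-computed so that
# -Inf sentinels are handled like any tied worst value.
.mw_auc <- function(pos, neg) {
  r <- rank(c(pos, neg))
  n1 <- length(pos)
  n2 <- length(neg)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' @export
print.significance_result <- function(x, ...) {
  cat(sprintf("%s: p = %.4g (AUC %.3f)\n", x$method, x$p_value, x$auc))
  invisible(x)
}

#' Count negative pairs that appear in the positive set
#'
#' Verifies the disjointness of a sampled negative (source, target) pair
#' list from the verified positive pairs; a sound negative set returns 0.
#'
#' @param positives,negatives Data frames with `source_accession` and
#'   `target_accession` columns.
#' @return Number of negative ordered pairs present among the positives.
#' @export
disjointness_check <- function(positives, negatives) {
  key <- function(df) paste(df$source_accession, df$target_accession, sep = "\r")
  sum(key(negatives) %in% key(positives))
}
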