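#' Confusion counts for binary predictions
#'
#' @param labels True labels, coercible to 0/1 (1 = positive).
#' @param predictions Predicted labels, coercible to 0/1.
#' @return One-row tibble with columns `tp`, `tn`, `fp`, `fn`.
#' @export
confusion_counts <- function(labels, predictions) {
  assert_that(length(labels) == length(predictions) && length(labels) > 0,
              "labels and predictions must be equal-length and non-empty")
  y <- as.integer(labels)
  p <- as.integer(predictions)
  assert_that(all(y %in% c(0L, 1L)) && all(p %in% c(0L, 1L)),
              "labels and predictions must be binary (0/1)")
  tibble::tibble(
    tp = sum(y == 1L & p == 1L),
    tn = sum(y == 0L & p == 0L),
    fp = sum(y == 0L & p == 1L),
    fn = sum(y == 1L & p == 0L)
  )
}

#' Scalar classification metrics from confusion counts
#'
#' Accuracy `(TP+TN)/n`, sensitivity (= TPR = recall) `TP/(TP+FN)`,
#' specificity `TN/(FP+TN)`, false positive rate `FP/(FP+TN)` and precision
#' `TP/(TP+FP)`. A metric whose denominator is zero is undefined and reported
#' as `NA`, never silently as 0.
#'
#' @param counts One-row tibble or list with `tp`, `tn`, `fp`, `fn`.
#' @return One-row tibble with `acc`, `sen`, `spe`, `fpr`, `precision`.
#' @export
scalar_metrics <- function(counts) {
  tp <- counts$tp; tn <- counts$tn; fp <- counts$fp; fn <- counts$fn
  n <- tp + tn + fp + fn
  assert_that(n > 0, "confusion counts sum to zero")
  safe_div <- function(num, den) if (den == 0) NA_real_ else num / den
  tibble::tibble(
    acc = safe_div(tp + tn, n),
    sen = safe_div(tp, tp + fn),
    spe = safe_div(tn, fp + tn),
    fpr = safe_div(fp, fp + tn),
    precision = safe_div(tp, tp + fp)
  )
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC: the probability that a random positive is
#' scored above a random negative, with ties given half credit.
#'
#' @param labels Binary true labels (1 = positive); both classes required.
#' @param scores Numeric scores, higher = more positive.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(labels, scores) {
  y <- as.integer(labels)
  assert_that(length(y) == length(scores) && length(y) > 0,
              "labels and scores must be equal-length and non-empty")
  npos <- sum(y == 1L)
  nneg <- sum(y == 0L)
  assert_that(npos > 0 && nneg > 0,
              "AUROC undefined: both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Area under the precision-recall curve
#'
#' Step-curve area over descending score thresholds (no linear
#' interpolation): at each distinct score, precision and recall are computed
#' on the "predict positive at or above this score" rule, and the area is the
#' sum of precision times the recall increment.
#'
#' @param labels Binary true labels (1 = positive); at least one positive
#'   required.
#' @param scores Numeric scores, higher = more positive.
#' @return AUPR in `(0, 1]`.
#' @export
aupr <- function(labels, scores) {
  y <- as.integer(labels)
  assert_that(length(y) == length(scores) && length(y) > 0,
              "labels and scores must be equal-length and non-empty")
  npos <- sum(y == 1L)
  assert_that(npos > 0, "AUPR undefined: no positive labels")
  ord <- order(scores, decreasing = TRUE)
  y <- y[ord]
  s <- scores[ord]
  # threshold group ends = last index of each distinct score
  grp_end <- which(!duplicated(s, fromLast = TRUE))
  tp <- cumsum(y)[grp_end]
  pred_pos <- grp_end
  precision <- tp / pred_pos
  recall <- tp / npos
  prev_recall <- c(0, head(recall, -1))
  sum(precision * (recall - prev_recall))
}

#' Evaluate scores against labels with all supported metrics
#'
#' Convenience wrapper: thresholds scores at `cutoff` (inclusive on the
#' positive side), then reports confusion counts, scalar metrics, AUROC and
#' AUPR in one row.
#'
#' @param labels Binary true labels.
#' @param scores Numeric scores in `[0, 1]`.
#' @param cutoff Probability cutoff for the scalar metrics. Default 0.5.
#' @return One-row tibble.
#' @export
evaluate_predictions <- function(labels, scores, cutoff = 0.5) {
  pred <- as.integer(scores >= cutoff)
  cc <- confusion_counts(labels, pred)
  sm <- scalar_metrics(cc)
  both <- length(unique(as.integer(labels))) == 2L
  dplyr::bind_cols(
    cc, sm,
    tibble::tibble(
      auroc = if (both) auroc(labels, scores) else NA_real_,
      aupr = if (any(as.integer(labels) == 1L)) aupr(labels, scores) else NA_real_
    )
  )
}
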