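# Threshold-free and threshold classification metrics.

#' Area under the ROC curve
#'
#' Computed through the Mann-Whitney identity: the probability that a
#' random positive outscores a random negative, ties counted half.
#'
#' @param scores real-valued scores (higher = more positive).
#' @param labels 0/1 labels.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stopf("auroc needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve
#'
#' Average-precision convention: the sum over distinct score thresholds
#' of the recall increment times the precision at that threshold.
#'
#' @inheritParams auroc
#' @return AUPRC in (0, 1\].
#' @export
auprc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n_pos <- sum(labels == 1)
  if (n_pos == 0) stopf("auprc needs at least one positive")
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]; sc <- scores[ord]
  # collapse tied scores into single thresholds
  grp_end <- cumsum(rle(sc)$lengths)
  tp <- cumsum(lab)[grp_end]
  n_at <- grp_end
  precision <- tp / n_at
  recall <- tp / n_pos
  sum(diff(c(0, recall)) * precision)
}

#' Confusion-matrix metrics at a fixed threshold
#'
#' Predictions are positive when `score >= threshold`. With no predicted
#' positives, precision is defined as 0 with a warning.
#'
#' @inheritParams auroc
#' @param threshold decision threshold (default 0.5).
#' @return named vector `c(f1, precision, recall)`.
#' @export
threshold_metrics <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels))
  pred <- as.numeric(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  precision <- if (tp + fp == 0) {
    warnf("no predicted positives at threshold %.3g; precision set to 0", threshold)
    0
  } else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(f1 = f1, precision = precision, recall = recall)
}
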