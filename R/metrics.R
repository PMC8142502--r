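#' Binary classification metrics from confusion counts
#'
#' Computes accuracy, precision, recall, F-measure and the Matthews
#' correlation coefficient from true/false positive/negative counts, with
#' the moonlighting class as positive:
#'
#' * `acc = (TP + TN) / (TP + FP + TN + FN)`
#' * `precision = TP / (TP + FP)` (0 when the denominator is 0)
#' * `recall = TP / (TP + FN)` (0 when the denominator is 0)
#' * `f_measure = 2 * precision * recall / (precision + recall)` (0 when
#'   both are 0)
#' * `mcc = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))` (0 when
#'   any factor of the denominator is 0)
#'
#' When `scores` and `labels` are supplied, the ROC AUC is added as the
#' rank-based (Mann-Whitney) probability that a random positive scores
#' above a random negative, ties counted half.
#'
#' @param tp,fp,tn,fn Non-negative confusion counts (scalars).
#' @param scores Optional numeric positive-class scores.
#' @param labels Optional logical (or MP/NONMP character) vector, `TRUE`
#'   for the positive class, parallel to `scores`.
#' @return One-row tibble with columns `acc`, `precision`, `recall`,
#'   `f_measure`, `mcc` and (when scores are given) `auc`.
#' @examples
#' compute_metrics(tp = 3, fp = 1, tn = 4, fn = 2)
#' @export
compute_metrics <- function(tp, fp, tn, fn, scores = NULL, labels = NULL) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  stopifnot(all(counts >= 0), all(counts == round(counts)))
  n <- sum(counts)
  if (n == 0) stop("all confusion counts are zero", call. = FALSE)
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  denom <- prod(c(tp + fp, tp + fn, tn + fp, tn + fn))
  mcc <- if (denom > 0) (tp * tn - fp * fn) / sqrt(denom) else 0
  out <- tibble(acc = (tp + tn) / n, precision = precision, recall = recall,
                f_measure = f, mcc = mcc)
  if (!is.null(scores)) {
    out$auc <- auc_rank(scores, labels)
  }
  out
}

#' Rank-based ROC AUC
#'
#' Mann-Whitney statistic: the probability that a randomly chosen positive
#' receives a higher score than a randomly chosen negative, ties counted
#' one half. Equivalent to the area under the empirical ROC curve.
#'
#' @inheritParams compute_metrics
#' @return AUC in `[0, 1]`.
#' @examples
#' auc_rank(c(0.9, 0.8, 0.3, 0.1), c(TRUE, TRUE, FALSE, FALSE))  # 1
#' @export
auc_rank <- function(scores, labels) {
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels) == "MP"
  }
  stopifnot(length(scores) == length(labels), is.logical(labels))
  npos <- sum(labels)
  nneg <- sum(!labels)
  if (npos == 0L || nneg == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - npos * (npos + 1) / 2) / (npos * nneg)
}

# pooled confusion counts + AUC for a block of predictions
metrics_from_predictions <- function(truth, predicted, scores = NULL) {
  pos <- truth == "MP"
  ppos <- predicted == "MP"
  compute_metrics(tp = sum(pos & ppos), fp = sum(!pos & ppos),
                  tn = sum(!pos & !ppos), fn = sum(pos & !ppos),
                  scores = scores,
                  labels = if (is.null(scores)) NULL else pos)
}
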