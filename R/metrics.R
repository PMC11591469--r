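#' Rank-based AUC with tie averaging
#'
#' Probability that a random positive outscores a random negative, with ties
#' counted half (equivalent to the Wilcoxon statistic).
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 labels; both classes must be present.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) stop("AUC undefined with a single class")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (step integral)
#'
#' Sorts by decreasing score and accumulates `precision * delta_recall`
#' at each threshold step.
#'
#' @inheritParams auc_score
#' @return AUPRC in \[0, 1\].
#' @export
auprc_score <- function(scores, labels) {
  labels <- as.numeric(labels)
  n1 <- sum(labels == 1)
  if (n1 == 0L) stop("AUPRC undefined without positives")
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]
  tp <- cumsum(y)
  prec <- tp / seq_along(y)
  rec <- tp / n1
  sum(prec * diff(c(0, rec)))
}

#' Threshold and ranking metrics for a score table
#'
#' Computes rank-based AUC, the precision-recall step integral, and
#' accuracy / F1 / recall / precision at the given score threshold.
#'
#' @param table A data frame with `score` and `label` columns (labels 0/1),
#'   e.g. the score table of a fit.
#' @param threshold Classification cut-off for the thresholded metrics.
#' @return A one-row tibble: `acc`, `f1`, `recall`, `precision`, `auc`,
#'   `auprc`, `n`.
#' @export
evaluate_scores <- function(table, threshold = 0.5) {
  scores <- table$score
  labels <- as.numeric(table$label)
  pred <- as.numeric(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  tn <- sum(pred == 0 & labels == 0)
  prec <- if (tp + fp > 0) tp / (tp + fp) else 0
  rec <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
  tibble::tibble(
    acc = (tp + tn) / length(labels),
    f1 = f1,
    recall = rec,
    precision = prec,
    auc = auc_score(scores, labels),
    auprc = auprc_score(scores, labels),
    n = length(labels)
  )
}

#' Mean binary cross-entropy loss
#'
#' `-(1/n) sum(y log p + (1 - y) log(1 - p))` with probabilities clamped to
#' `[eps, 1 - eps]`.
#'
#' @param scores Predicted probabilities.
#' @param labels 0/1 labels.
#' @param eps Clamp width.
#' @return Non-negative loss value.
#' @export
bce_loss <- function(scores, labels, eps = 1e-7) {
  if (length(scores) == 0L) stop("empty input")
  if (length(scores) != length(labels)) stop("length mismatch")
  p <- pmin(pmax(scores, eps), 1 - eps)
  y <- as.numeric(labels)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}
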