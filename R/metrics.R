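# Bag-level evaluation: ROC/AUC by trapezoidal integration and the
# threshold metrics accuracy, recall, precision, F1 with the confusion
# matrix. Positive class = abnormal (label 1).

#' ROC curve points
#'
#' Sweeps the decision threshold over every distinct score (ties grouped, so
#' tied scores produce diagonal ROC segments and therefore half credit in
#' the area) and returns the (fpr, tpr, threshold) points from (0, 0) to
#' (1, 1).
#'
#' @param labels 0/1 vector.
#' @param scores numeric scores, higher = more abnormal.
#' @return data.frame with columns fpr, tpr, threshold.
#' @export
rocPoints <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  nPos <- sum(labels == 1)
  nNeg <- sum(labels == 0)
  if (nPos == 0 || nNeg == 0)
    stop("ROC needs both classes", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  last <- cumsum(rle(s)$lengths)        # last index of each tie group
  tp <- cumsum(y == 1)[last]
  fp <- cumsum(y == 0)[last]
  data.frame(fpr = c(0, fp / nNeg), tpr = c(0, tp / nPos),
             threshold = c(Inf, s[last]))
}

#' Area under the ROC curve
#'
#' Trapezoidal integration of [rocPoints()]. Equals the Mann-Whitney
#' rank statistic P(score_pos > score_neg) + 0.5 P(tie). Returns NA when a
#' class is absent.
#'
#' @inheritParams rocPoints
#' @return numeric AUC in [0, 1], or NA.
#' @export
aucTrapezoid <- function(labels, scores) {
  if (length(unique(labels)) < 2L) return(NA_real_)
  r <- rocPoints(labels, scores)
  sum(diff(r$fpr) * (head(r$tpr, -1) + tail(r$tpr, -1)) / 2)
}

#' Threshold metrics and confusion matrix for scored bags
#'
#' Computes AUC (threshold-free), plus accuracy, recall, precision and F1 at
#' the given threshold (prediction = abnormal when score >= threshold), and
#' the 2x2 confusion matrix. With only one class present the AUC is NA and
#' the remaining metrics are still computed.
#'
#' @param labels 0/1 vector.
#' @param scores numeric scores in [0, 1].
#' @param threshold decision threshold (default 0.5).
#' @return list with auc, accuracy, recall, precision, f1, confusion (2x2
#'   integer matrix, rows = truth, cols = prediction) and roc (data.frame,
#'   NULL if single-class).
#' @examples
#' evaluateScores(c(1, 1, 0), c(0.9, 0.8, 0.1))
#' @export
evaluateScores <- function(labels, scores, threshold = 0.5) {
  pred <- as.integer(scores >= threshold)
  tp <- sum(labels == 1 & pred == 1)
  fn <- sum(labels == 1 & pred == 0)
  fp <- sum(labels == 0 & pred == 1)
  tn <- sum(labels == 0 & pred == 0)
  confusion <- matrix(as.integer(c(tn, fn, fp, tp)), 2L, 2L,
                      dimnames = list(truth = c("normal", "abnormal"),
                                      pred = c("normal", "abnormal")))
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  f1 <- if (!is.na(recall) && !is.na(precision) && recall + precision > 0)
    2 * precision * recall / (precision + recall) else NA_real_
  both <- length(unique(labels)) == 2L
  list(auc = if (both) aucTrapezoid(labels, scores) else NA_real_,
       accuracy = (tp + tn) / length(labels),
       recall = recall, precision = precision, f1 = f1,
       confusion = confusion,
       roc = if (both) rocPoints(labels, scores) else NULL)
}

#' Evaluate a model on a list of bags
#'
#' Runs [forwardBag()] on every bag and summarizes with [evaluateScores()].
#'
#' @param model a [MILModel-class].
#' @param bags list of labeled [MILBag-class] objects.
#' @param threshold decision threshold.
#' @return as [evaluateScores()], plus \code{scores} and \code{labels}.
#' @export
evaluateBags <- function(model, bags, threshold = 0.5) {
  if (!length(bags)) stop("no bags to evaluate", call. = FALSE)
  scores <- vapply(bags, function(b) forwardBag(model, b)$bagProbability,
                   numeric(1))
  labels <- vapply(bags, bagLabel, integer(1))
  out <- evaluateScores(labels, scores, threshold)
  out$scores <- scores
  out$labels <- labels
  out
}
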