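#' Confusion counts at a score threshold
#'
#' Predictions are positive exactly when \code{score > threshold} (strict:
#' a score equal to the threshold is predicted negative).
#'
#' @param scores numeric decision scores.
#' @param truth vector of true labels (+1/-1, or any encoding accepted by
#'   \code{\link{PeptideSet}}).
#' @param threshold decision threshold, default 0.
#' @return Named integer vector with elements \code{TP}, \code{TN},
#'   \code{FP}, \code{FN}.
#' @examples
#' confusionCounts(c(1, -1, 0.5, -0.2), c(1, -1, -1, 1))
#' @export
confusionCounts <- function(scores, truth, threshold = 0) {
  if (length(scores) == 0L) stop("empty input")
  if (length(scores) != length(truth))
    stop("scores and truth must have equal length")
  y <- normalizeLabels(truth)
  pred <- ifelse(scores > threshold, 1L, -1L)
  c(TP = sum(pred == 1L & y == 1L), TN = sum(pred == -1L & y == -1L),
    FP = sum(pred == 1L & y == -1L), FN = sum(pred == -1L & y == 1L))
}

#' Accuracy, Matthews correlation and AUC
#'
#' \deqn{ACC = \frac{TP + TN}{TP + TN + FP + FN}}
#' \deqn{MCC = \frac{TP \cdot TN - FP \cdot FN}
#'   {\sqrt{(TP+FN)(TP+FP)(TN+FP)(TN+FN)}}}
#' and the AUC is the Mann-Whitney statistic of the scores: the fraction of
#' (positive, negative) pairs ranked concordantly, ties counted half. An MCC
#' denominator of zero (a degenerate confusion matrix) yields MCC = 0 with a
#' logged warning.
#'
#' @param scores numeric decision scores.
#' @param truth true labels; both classes must be present for MCC/AUC to be
#'   meaningful.
#' @param threshold decision threshold for the confusion counts (default 0).
#' @param counts optional precomputed \code{\link{confusionCounts}}.
#' @return Named numeric vector \code{c(ACC=, MCC=, AUC=)}.
#' @examples
#' computeMetrics(c(0.9, 0.8, 0.4, 0.7, 0.3), c(1, 1, 1, -1, -1))
#' @export
computeMetrics <- function(scores, truth, threshold = 0, counts = NULL) {
  y <- normalizeLabels(truth)
  if (is.null(counts)) counts <- confusionCounts(scores, y, threshold)
  acc <- (counts[["TP"]] + counts[["TN"]]) / sum(counts)
  mcc <- mccFromCounts(counts)
  auc <- aucScore(scores, y)
  c(ACC = acc, MCC = mcc, AUC = auc)
}

mccFromCounts <- function(counts) {
  TP <- as.numeric(counts[["TP"]]); TN <- as.numeric(counts[["TN"]])
  FP <- as.numeric(counts[["FP"]]); FN <- as.numeric(counts[["FN"]])
  den <- sqrt((TP + FN) * (TP + FP) * (TN + FP) * (TN + FN))
  if (den == 0) {
    logMsg("warn", "MCC denominator is zero; returning 0")
    return(0)
  }
  (TP * TN - FP * FN) / den
}

#' @describeIn computeMetrics AUC alone (rank/Mann-Whitney estimator with
#'   half credit for ties).
#' @export
aucScore <- function(scores, truth) {
  y <- normalizeLabels(truth)
  npos <- sum(y == 1L)
  nneg <- sum(y == -1L)
  if (npos == 0L || nneg == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[y == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
}
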