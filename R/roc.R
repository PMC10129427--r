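#' @include accessors.R
NULL

#' ROC curve, AUC and Hanley-McNeil confidence interval
#'
#' Threshold sweep over the unique scores (a case is called positive when
#' its score is >= the threshold), trapezoidal AUC, and a 95% confidence
#' interval from the Hanley-McNeil standard-error formula. The AUC equals
#' the Mann-Whitney U of the positive group (midranks for ties) divided by
#' n1 * n2, so a positive group that tends to score higher gives AUC > 0.5.
#'
#' @param scores numeric scores.
#' @param labels class labels, two classes.
#' @param positive the label treated as the positive class.
#' @return A [ROCCurve-class].
#' @examples
#' rocAuc(c(1, 2, 3, 4), c("a", "a", "b", "b"), positive = "b")
#' @export
rocAuc <- function(scores, labels, positive) {
  scores <- as.numeric(scores)
  labels <- as.character(labels)
  if (length(scores) != length(labels))
    stop("label error: scores and labels must have equal length")
  pos <- labels == positive
  if (!any(pos) || all(pos))
    stop("label error: both classes must be present (positive = '",
         positive, "')")
  n1 <- sum(pos); n2 <- sum(!pos)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), 0)
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), 0)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
              (n2 - 1) * (q2 - auc^2)) / (n1 * n2))
  new("ROCCurve", thresholds = thr, tpr = tpr, fpr = fpr, auc = auc,
      ciLow = max(0, auc - 1.959964 * se), ciHigh = min(1, auc + 1.959964 * se),
      n1 = as.integer(n1), n2 = as.integer(n2))
}
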