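#' Area under the ROC curve
#'
#' The probability that a uniformly chosen positive outscores a uniformly
#' chosen negative, with ties counted one half — computed from the rank
#' sum, so it equals the normalized Mann-Whitney U statistic exactly.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels 0/1 labels; both classes must be present.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (length(scores) != length(labels))
    stopf("scores and labels differ in length")
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  if (n_pos == 0L || n_neg == 0L)
    stopf("roc_auc needs both classes present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' F1 score at a threshold
#'
#' Harmonic mean of precision and recall for predictions
#' `scores >= threshold`; 0 by convention when there are no positive
#' predictions or no true positives.
#'
#' @param scores Numeric scores.
#' @param labels 0/1 labels.
#' @param threshold Decision threshold (default 0.5; predictions use
#'   `>=`).
#' @return F1 in \[0, 1\].
#' @export
f1_score <- function(scores, labels, threshold = 0.5) {
  labels <- as.numeric(labels)
  pred <- as.numeric(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  if (tp == 0) return(0)
  prec <- tp / (tp + fp)
  rec <- tp / (tp + fn)
  2 * prec * rec / (prec + rec)
}
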