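#' Confusion counts from aligned binary label vectors
#'
#' @param predicted,truth Equal-length vectors with values in `{0, 1}`;
#'   1 is the senescent (positive) class.
#' @return An object of class `confusion_counts`: list with `TP`, `TN`,
#'   `FP`, `FN` (their sum equals the input length).
#' @export
confusion <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stop("predicted and truth must have equal length", call. = FALSE)
  }
  if (!all(predicted %in% c(0, 1)) || !all(truth %in% c(0, 1))) {
    stop("labels must be 0 or 1", call. = FALSE)
  }
  structure(list(
    TP = sum(predicted == 1 & truth == 1),
    TN = sum(predicted == 0 & truth == 0),
    FP = sum(predicted == 1 & truth == 0),
    FN = sum(predicted == 0 & truth == 1)
  ), class = "confusion_counts")
}

#' Classification performance metrics
#'
#' Accuracy `(TN + TP) / (TN + TP + FP + FN)`, precision `TP / (TP + FP)`,
#' recall `TP / (TP + FN)` and the F1 score, the harmonic mean
#' `2 * precision * recall / (precision + recall)`. Ratios with a zero
#' denominator are reported as `NA` with a flag in `undefined`, never
#' silently as zero; by declared convention F1 is 0 when precision and
#' recall are both defined and sum to 0.
#'
#' @param cc A `confusion_counts` object (or list with TP/TN/FP/FN).
#' @return List with `accuracy`, `precision`, `recall`, `f1` and
#'   `undefined` (character vector naming any undefined metrics).
#' @export
classification_metrics <- function(cc) {
  tp <- cc$TP; tn <- cc$TN; fp <- cc$FP; fn <- cc$FN
  if (any(c(tp, tn, fp, fn) < 0)) stop("negative counts", call. = FALSE)
  n <- tp + tn + fp + fn
  if (n == 0) stop("all confusion counts are zero", call. = FALSE)
  undefined <- character()
  accuracy <- (tn + tp) / n
  precision <- if (tp + fp > 0) tp / (tp + fp) else {
    undefined <- c(undefined, "precision"); NA_real_
  }
  recall <- if (tp + fn > 0) tp / (tp + fn) else {
    undefined <- c(undefined, "recall"); NA_real_
  }
  f1 <- if (is.na(precision) || is.na(recall)) {
    undefined <- c(undefined, "f1"); NA_real_
  } else if (precision + recall == 0) {
    0 # declared convention
  } else {
    2 * precision * recall / (precision + recall)
  }
  list(accuracy = accuracy, precision = precision, recall = recall,
       f1 = f1, undefined = undefined)
}

# AUC as the Mann-Whitney exceedance probability with half credit for ties
auc_mann_whitney <- function(scores, truth) {
  n1 <- sum(truth == 1)
  n0 <- sum(truth == 0)
  if (n1 == 0 || n0 == 0) {
    stop("AUC requires both classes in 'truth'", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[truth == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC and precision-recall curves with AUC
#'
#' The AUC equals the Mann-Whitney exceedance probability
#' `P(score_pos > score_neg) + 0.5 P(tie)`; the ROC curve is swept over
#' all distinct score thresholds.
#'
#' @param scores Real-valued scores (higher = more senescent).
#' @param truth Binary labels; both classes must be present.
#' @return List with `auc`, `roc` (data frame `threshold`, `fpr`, `tpr`)
#'   and `pr` (data frame `threshold`, `recall`, `precision`).
#' @export
roc_pr <- function(scores, truth) {
  if (length(scores) != length(truth)) {
    stop("scores and truth must have equal length", call. = FALSE)
  }
  if (!all(truth %in% c(0, 1)) || length(unique(truth)) < 2L) {
    stop("truth must be binary with both classes present", call. = FALSE)
  }
  auc <- auc_mann_whitney(scores, truth)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  n1 <- sum(truth == 1); n0 <- sum(truth == 0)
  tpr <- vapply(thr, function(t) sum(scores >= t & truth == 1) / n1, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & truth == 0) / n0, numeric(1))
  npred <- vapply(thr, function(t) sum(scores >= t), numeric(1))
  prec <- ifelse(npred > 0,
                 vapply(thr, function(t) sum(scores >= t & truth == 1),
                        numeric(1)) / pmax(npred, 1), NA_real_)
  list(auc = auc,
       roc = data.frame(threshold = thr, fpr = fpr, tpr = tpr),
       pr = data.frame(threshold = thr, recall = tpr, precision = prec))
}

#' Kolmogorov-Smirnov distance between two samples
#'
#' The sup-norm distance between the two empirical cumulative distribution
#' functions, `D = sup_x |ECDF_A(x) - ECDF_B(x)|`, as used to compare
#' per-feature distributions of control and senescent nuclei.
#'
#' @param a,b Non-empty numeric samples.
#' @return The D statistic in `[0, 1]`.
#' @export
compare_distributions <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  grid <- sort(unique(c(a, b)))
  fa <- stats::ecdf(a)(grid)
  fb <- stats::ecdf(b)(grid)
  max(abs(fa - fb))
}
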