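# Binary-classification metrics. AUROC is computed by trapezoidal integration
# of the ROC curve and AUPRC as the step-wise average precision; accuracy,
# sensitivity, specificity and precision are reported at the threshold that
# maximizes F1. (The source equations for sensitivity/specificity circulate in
# garbled printed forms; the standard definitions TP/(TP+FN) and TN/(TN+FP)
# are implemented.)

roc_curve_points <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  lab <- labels[ord]
  sc <- scores[ord]
  # step only between distinct score values (ties processed as one block)
  keep <- c(sc[-length(sc)] != sc[-1], TRUE)
  tp <- cumsum(lab)[keep]
  fp <- cumsum(1 - lab)[keep]
  P <- sum(labels); N <- length(labels) - P
  list(tpr = c(0, tp / P), fpr = c(0, fp / N),
       precision = tp / (tp + fp), recall = tp / P)
}

#' Area under the ROC curve
#'
#' Trapezoidal integration over the empirical ROC curve; equals the
#' probability that a random positive outscores a random negative (ties
#' counted half).
#'
#' @param scores numeric vector; @param labels 0/1 vector of the same length
#'   containing both classes.
#' @export
auroc <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (length(unique(labels)) < 2L)
    stop("auroc: AUROC undefined with a single class present")
  r <- roc_curve_points(scores, labels)
  sum(diff(r$fpr) * (utils::head(r$tpr, -1) + utils::tail(r$tpr, -1)) / 2)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise summation `sum_i (R_i - R_{i-1}) P_i` over distinct-score
#' thresholds.
#'
#' @inheritParams auroc
#' @export
auprc <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (sum(labels) == 0) stop("auprc: no positive labels")
  r <- roc_curve_points(scores, labels)
  sum(diff(c(0, r$recall)) * r$precision)
}

#' F1-optimal decision threshold
#'
#' Evaluates F1 at the midpoint between every pair of consecutive distinct
#' scores (plus one candidate below the minimum, so the all-positive rule is
#' reachable); a prediction is positive when `score >= threshold`. Ties in F1
#' break toward the lower threshold.
#'
#' @inheritParams auroc
#' @return the selected threshold (numeric scalar).
#' @export
optimal_f1_threshold <- function(scores, labels) {
  labels <- as.numeric(labels)
  su <- sort(unique(scores))
  cand <- c(su[1] - 1, if (length(su) > 1) (su[-1] + su[-length(su)]) / 2)
  f1 <- vapply(cand, function(t) {
    pred <- as.numeric(scores >= t)
    tp <- sum(pred == 1 & labels == 1)
    if (tp == 0) return(0)
    prec <- tp / sum(pred == 1)
    rec <- tp / sum(labels == 1)
    2 * prec * rec / (prec + rec)
  }, numeric(1))
  cand[which.max(f1)]  # which.max takes the first (lowest) on ties
}

#' Evaluate binary classification metrics
#'
#' Threshold-free AUROC/AUPRC plus confusion counts, accuracy, sensitivity
#' (TP/(TP+FN)), specificity (TN/(TN+FP)), precision and F1 at the F1-optimal
#' threshold.
#'
#' @inheritParams auroc
#' @param threshold decision threshold; default `NULL` selects the F1-optimal
#'   one via [optimal_f1_threshold()].
#' @return object of class `eval_metrics` (a named list).
#' @export
compute_metrics <- function(scores, labels, threshold = NULL) {
  labels <- as.numeric(labels)
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  if (is.null(threshold)) threshold <- optimal_f1_threshold(scores, labels)
  pred <- as.numeric(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1); tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  sens <- tp / (tp + fn)
  f1 <- if (!is.na(prec) && prec + sens > 0) 2 * prec * sens / (prec + sens) else 0
  structure(list(
    TP = tp, TN = tn, FP = fp, FN = fn,
    auroc = auroc(scores, labels), auprc = auprc(scores, labels),
    accuracy = (tp + tn) / (tp + tn + fp + fn),
    sensitivity = sens,
    specificity = tn / (tn + fp),
    precision = prec, f1 = f1, threshold = threshold),
    class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf(
    "AUROC %.3f | AUPRC %.3f | Acc %.3f | Sens %.3f | Spec %.3f (thr %.4f)\n",
    x$auroc, x$auprc, x$accuracy, x$sensitivity, x$specificity, x$threshold))
  cat(sprintf("  TP %d  FP %d  TN %d  FN %d\n", x$TP, x$FP, x$TN, x$FN))
  invisible(x)
}
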