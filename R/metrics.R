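# Classification metrics: confusion-matrix summaries, the ROC curve,
# AUROC with bootstrap confidence intervals.

#' Build a confusion matrix from truth and predicted labels
#'
#' @param truth Logical (or 0/1) vector of true positive-class membership.
#' @param predicted Logical (or 0/1) vector of predicted labels.
#' @return A list of class `confusion_matrix` with `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_matrix <- function(truth, predicted) {
  truth <- as.logical(truth); predicted <- as.logical(predicted)
  stopifnot(length(truth) == length(predicted), !anyNA(truth), !anyNA(predicted))
  structure(list(tp = sum(truth & predicted), fp = sum(!truth & predicted),
                 fn = sum(truth & !predicted), tn = sum(!truth & !predicted)),
            class = "confusion_matrix")
}

#' Confusion-matrix performance metrics
#'
#' Balanced accuracy is the mean of sensitivity (recall) and specificity;
#' recall is `tp / (tp + fn)`; precision is `tp / (tp + fp)`; F1 is the
#' harmonic mean of precision and recall. A metric whose denominator is
#' zero is reported as `NA`, never silently as 0.
#'
#' @param cm A `confusion_matrix`, or a list with `tp`, `fp`, `fn`, `tn`.
#' @return Named numeric vector `balanced_accuracy`, `recall`, `precision`,
#'   `f1`.
#' @export
#' @examples
#' confusion_metrics(list(tp = 33, fp = 15, fn = 11, tn = 58))
confusion_metrics <- function(cm) {
  stopifnot(all(c("tp", "fp", "fn", "tn") %in% names(cm)))
  tp <- cm$tp; fp <- cm$fp; fn <- cm$fn; tn <- cm$tn
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  recall <- div(tp, tp + fn)
  spec <- div(tn, tn + fp)
  precision <- div(tp, tp + fp)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  c(balanced_accuracy = mean(c(recall, spec)), recall = recall,
    precision = precision, f1 = f1)
}

#' Area under the ROC curve
#'
#' Rank-based AUROC: the tie-corrected probability that a random positive
#' scores above a random negative (ties count one half). This equals
#' trapezoidal integration of the empirical ROC curve.
#'
#' @param scores Numeric prediction scores (higher = more positive).
#' @param labels Logical/0-1 true labels; both classes must be present.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(scores), !anyNA(labels))
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Empirical ROC curve
#'
#' Sensitivity against 1 - specificity over all score thresholds.
#'
#' @inheritParams auroc
#' @return A data.frame with columns `threshold`, `fpr`, `tpr`, ordered by
#'   decreasing threshold (both coordinates non-decreasing).
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.logical(labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # collapse tied thresholds
  keep <- !duplicated(s)
  tps <- cumsum(y); fps <- cumsum(!y)
  idx <- c(which(keep)[-1] - 1L, length(s))
  data.frame(threshold = c(Inf, s[keep]),
             fpr = c(0, fps[idx] / sum(!y)),
             tpr = c(0, tps[idx] / sum(y)))
}

#' Bootstrap confidence interval for AUROC
#'
#' Stratified bootstrap: positives and negatives are resampled separately,
#' preserving the class balance; the interval is the percentile interval
#' of the resampled AUROCs.
#'
#' @inheritParams auroc
#' @param n_boot Number of bootstrap resamples (default 2000).
#' @param conf Confidence level (default 0.95).
#' @return A list with `auroc`, `ci` (length-2 vector), `n_boot`.
#' @export
auroc_ci <- function(scores, labels, n_boot = 2000, conf = 0.95) {
  labels <- as.logical(labels)
  pos <- which(labels); neg <- which(!labels)
  point <- auroc(scores, labels)
  boots <- vapply(seq_len(n_boot), function(b) {
    i <- c(sample(pos, replace = TRUE), sample(neg, replace = TRUE))
    auroc(scores[i], labels[i])
  }, numeric(1))
  a <- (1 - conf) / 2
  list(auroc = point,
       ci = unname(stats::quantile(boots, c(a, 1 - a))),
       n_boot = n_boot)
}

# threshold scores at 0.5 (ties classified positive) and compute all metrics
threshold_metrics <- function(scores, labels, threshold = 0.5) {
  cm <- confusion_matrix(labels, scores >= threshold)
  c(confusion_metrics(cm), auroc = auroc(scores, labels))
}
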