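# Confusion-matrix metrics and ROC analysis.  Interacting pairs are the
# positive class throughout.

#' Confusion-matrix metrics
#'
#' Accuracy, sensitivity (recall of the interacting class), precision and
#' Matthews correlation coefficient from raw counts:
#' `Acc = (TP+TN)/N`, `Sen = TP/(TP+FN)`, `Pre = TP/(TP+FP)`,
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FN)(TN+FP)(TP+FP)(TN+FN))`.
#' A zero factor in the MCC denominator (or an empty predicted-positive
#' set for precision) yields 0 with a warning.
#'
#' @param tp,fp,tn,fn Nonnegative integer counts.
#' @return A one-row tibble: `tp`, `fp`, `tn`, `fn`, `acc`, `sen`, `pre`,
#'   `mcc`.
#' @examples
#' compute_metrics(40, 5, 45, 10)
#' @export
compute_metrics <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0, tp + fp + tn + fn > 0)
  total <- tp + fp + tn + fn
  acc <- (tp + tn) / total
  sen <- if (tp + fn > 0) tp / (tp + fn) else {
    warn("no actual positives: sensitivity undefined, reporting 0")
    0
  }
  pre <- if (tp + fp > 0) tp / (tp + fp) else {
    warn("no predicted positives: precision undefined, reporting 0")
    0
  }
  denom2 <- (tp + fn) * (tn + fp) * (tp + fp) * (tn + fn)
  mcc <- if (denom2 > 0) {
    (tp * tn - fp * fn) / sqrt(denom2)
  } else {
    warn("degenerate confusion matrix: MCC undefined, reporting 0")
    0
  }
  tibble::tibble(tp = tp, fp = fp, tn = tn, fn = fn,
                 acc = acc, sen = sen, pre = pre, mcc = mcc)
}

confusion_counts <- function(truth, predicted) {
  tibble::tibble(
    tp = sum(truth == 1 & predicted == 1),
    fp = sum(truth == 0 & predicted == 1),
    tn = sum(truth == 0 & predicted == 0),
    fn = sum(truth == 1 & predicted == 0)
  )
}

#' ROC curve points
#'
#' Sweeps the decision threshold over the unique score values (descending)
#' and records the false- and true-positive rates, starting at (0, 0) and
#' ending at (1, 1).
#'
#' @param scores Numeric scores; larger means more positive.
#' @param labels Binary labels (0/1, logical, or a two-level factor whose
#'   second level is positive).
#' @return A tibble with columns `threshold`, `fpr`, `tpr`.
#' @export
roc_points <- function(scores, labels) {
  labels <- as_binary_labels(labels)
  if (length(unique(labels)) < 2) {
    abort("ROC needs both classes present in the labels",
          class = "ppidvm_error_domain")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  l <- labels[ord]
  keep <- !duplicated(s, fromLast = TRUE)  # last index of each tied score
  tp <- cumsum(l)[keep]
  fp <- cumsum(1 - l)[keep]
  tibble::tibble(
    threshold = c(Inf, s[keep]),
    fpr = c(0, fp / sum(1 - labels)),
    tpr = c(0, tp / sum(labels))
  )
}

#' Area under the ROC curve
#'
#' Trapezoidal integration of the ROC curve of [roc_points()].  With tied
#' scores the trapezoid over the tie block counts ties as one half, so the
#' value equals the rank statistic: the probability that a random positive
#' outscores a random negative.
#'
#' @inheritParams roc_points
#' @return AUC in \[0, 1\].
#' @examples
#' roc_auc(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))
#' @export
roc_auc <- function(scores, labels) {
  pts <- roc_points(scores, labels)
  sum(diff(pts$fpr) * (head(pts$tpr, -1) + pts$tpr[-1]) / 2)
}

as_binary_labels <- function(labels) {
  if (is.factor(labels)) {
    if (nlevels(labels) != 2) {
      abort("factor labels must have exactly two levels",
            class = "ppidvm_error_domain")
    }
    as.integer(labels) - 1L
  } else if (is.logical(labels)) {
    as.integer(labels)
  } else {
    l <- as.integer(labels)
    if (!all(l %in% c(0L, 1L))) {
      abort("labels must be binary 0/1", class = "ppidvm_error_domain")
    }
    l
  }
}
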