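#' Area under the ROC curve by pairwise concordance
#'
#' Rank-based estimator: the probability that a randomly chosen positive
#' scores higher than a randomly chosen negative, with ties credited 0.5
#' (equivalent to the Mann-Whitney U statistic).
#'
#' @param labels 0/1 vector.
#' @param scores numeric vector of the same length.
#' @return AUC in \[0, 1\], or `NA` if only one class is present.
#' @export
auc_concordance <- function(labels, scores) {
  stopifnot(length(labels) == length(scores), all(labels %in% c(0, 1)))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) {
    return(NA_real_)
  }
  r <- rank(scores) # average ranks handle ties as 0.5 credit
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (step rule)
#'
#' Scores are swept from high to low over their distinct values; at each
#' threshold the precision is weighted by the recall gained there (average
#' precision / step interpolation, not trapezoidal).
#'
#' @inheritParams auc_concordance
#' @return AUPRC in \[0, 1\], or `NA` if only one class is present.
#' @export
auprc_step <- function(labels, scores) {
  stopifnot(length(labels) == length(scores), all(labels %in% c(0, 1)))
  P <- sum(labels == 1)
  if (P == 0L || P == length(labels)) {
    return(NA_real_)
  }
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o]
  sc <- scores[o]
  tp <- cumsum(lab)
  fp <- cumsum(1 - lab)
  # only evaluate at the last index of each tied score block
  last <- c(sc[-1] != sc[-length(sc)], TRUE)
  tp <- tp[last]
  fp <- fp[last]
  prec <- tp / (tp + fp)
  rec <- tp / P
  sum(diff(c(0, rec)) * prec)
}

#' Classification metrics of scored pairs at a threshold
#'
#' @param labels 0/1 vector of true classes.
#' @param scores predicted probabilities.
#' @param threshold scores strictly above this are called positive
#'   (default 0.5, the repurposing cutoff).
#' @return A `metrics_report`: accuracy, precision, recall, f1, auc, auprc,
#'   confusion counts (`tp`, `fp`, `tn`, `fn`), `n`, `threshold`. `auc` and
#'   `auprc` are `NA` when only one class is present; `precision`/`f1` are
#'   `NA` when undefined (no positive calls).
#' @export
compute_metrics <- function(labels, scores, threshold = 0.5) {
  stopifnot(length(labels) == length(scores), length(labels) > 0L,
            all(labels %in% c(0, 1)))
  pred <- as.integer(scores > threshold)
  tp <- sum(pred == 1L & labels == 1)
  fp <- sum(pred == 1L & labels == 0)
  tn <- sum(pred == 0L & labels == 0)
  fn <- sum(pred == 0L & labels == 1)
  n <- length(labels)
  precision <- if (tp + fp > 0L) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0L) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    NA_real_
  }
  structure(
    list(
      accuracy = (tp + tn) / n,
      precision = precision,
      recall = recall,
      f1 = f1,
      auc = auc_concordance(labels, scores),
      auprc = auprc_step(labels, scores),
      tp = tp, fp = fp, tn = tn, fn = fn,
      n = n, threshold = threshold
    ),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    paste0(
      "metrics_report (n=%d, threshold=%.2f)\n",
      "  accuracy %.4f  precision %s  recall %s  f1 %s\n",
      "  auc %s  auprc %s   [tp=%d fp=%d tn=%d fn=%d]\n"
    ),
    x$n, x$threshold, x$accuracy,
    .fmt(x$precision), .fmt(x$recall), .fmt(x$f1),
    .fmt(x$auc), .fmt(x$auprc), x$tp, x$fp, x$tn, x$fn
  ))
  invisible(x)
}

.fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.4f", v)

#' Turn a metrics report into a one-row data.frame
#' @param x a `metrics_report`.
#' @param ... unused.
#' @return One-row data.frame of all fields.
#' @export
as.data.frame.metrics_report <- function(x, ...) {
  as.data.frame(unclass(x))
}
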