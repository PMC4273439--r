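#' Confusion counts with the "positive = normal" convention
#'
#' Screening devices of this kind report sensitivity to *normal* rhythm:
#' a true positive is a normal window recognised as normal, a true negative
#' is a diseased (atrial-fibrillation or ischemia) window recognised as
#' diseased.  This is the convention used by all pooled metrics in the
#' package.
#'
#' @param tp,fp,tn,fn non-negative integer counts.
#' @return an object of class `confusion_counts`.
#' @export
confusion_counts <- function(tp = 0, fp = 0, tn = 0, fn = 0) {
  v <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(!is.finite(v)) || any(v < 0) || any(v != round(v))) {
    stop("confusion counts must be non-negative integers", call. = FALSE)
  }
  structure(as.list(stats::setNames(as.integer(round(v)), names(v))),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  m <- confusion_metrics(x)
  cat(sprintf("<confusion_counts> tp=%d fp=%d tn=%d fn=%d (n=%d)\n",
              x$tp, x$fp, x$tn, x$fn, x$tp + x$fp + x$tn + x$fn))
  cat(sprintf("  sensitivity %.4f  specificity %.4f\n",
              m["sensitivity"], m["specificity"]))
  invisible(x)
}

#' Sensitivity and specificity from confusion counts
#'
#' `sensitivity = tp / (tp + fn)`, `specificity = tn / (tn + fp)`.  With the
#' positive-equals-normal convention, sensitivity is the fraction of normal
#' windows recognised as normal and specificity the fraction of diseased
#' windows recognised as diseased.  A zero denominator yields `NA` (the
#' metric is undefined), never an error.
#'
#' @param counts a `confusion_counts` object (or a list with fields
#'   `tp`, `fp`, `tn`, `fn`).
#' @return named numeric vector `c(sensitivity=, specificity=)`, values in
#'   `[0, 1]` or `NA`.
#' @examples
#' confusion_metrics(confusion_counts(tp = 95, fn = 5, tn = 96, fp = 4))
#' @export
confusion_metrics <- function(counts) {
  sens <- if ((counts$tp + counts$fn) > 0) counts$tp / (counts$tp + counts$fn) else NA_real_
  spec <- if ((counts$tn + counts$fp) > 0) counts$tn / (counts$tn + counts$fp) else NA_real_
  c(sensitivity = sens, specificity = spec)
}

#' Pool predicted vs. true window labels into confusion counts
#'
#' Windows whose prediction is `NA` (unusable windows) are dropped.  Any
#' diseased window predicted as *either* disease counts as a true negative:
#' the counts measure normal-vs-abnormal discrimination.
#'
#' @param truth,predicted vectors coercible to the package's class labels.
#' @return a `confusion_counts` object.
#' @export
count_confusion <- function(truth, predicted) {
  truth <- as_class_label(truth)
  predicted <- as_class_label(predicted)
  keep <- !is.na(truth) & !is.na(predicted)
  truth <- truth[keep]; predicted <- predicted[keep]
  pos_t <- truth == "normal"
  pos_p <- predicted == "normal"
  confusion_counts(tp = sum(pos_t & pos_p), fn = sum(pos_t & !pos_p),
                   tn = sum(!pos_t & !pos_p), fp = sum(!pos_t & pos_p))
}
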