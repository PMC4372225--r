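#' Confusion counts for binary activity predictions
#'
#' @param truth,prediction Character vectors of `"inhibitor"` /
#'   `"non_inhibitor"`; the inhibitor class is positive.
#' @return One-row tibble `tp`, `fp`, `tn`, `fn`.
#' @export
confusion_counts <- function(truth, prediction) {
  assert_labels(truth); assert_labels(prediction)
  if (length(truth) != length(prediction)) {
    abort("truth and prediction lengths differ")
  }
  tibble::tibble(
    tp = sum(truth == "inhibitor" & prediction == "inhibitor"),
    fp = sum(truth == "non_inhibitor" & prediction == "inhibitor"),
    tn = sum(truth == "non_inhibitor" & prediction == "non_inhibitor"),
    fn = sum(truth == "inhibitor" & prediction == "non_inhibitor")
  )
}

#' Standard binary classification metrics
#'
#' Sensitivity, specificity and accuracy as percentages, plus the Matthews
#' correlation coefficient
#' \deqn{MCC = \frac{tp \cdot tn - fp \cdot fn}
#'   {\sqrt{(tp+fp)(tp+fn)(tn+fp)(tn+fn)}}}
#' with the convention MCC = 0 when any factor of the denominator is zero.
#'
#' @param counts One-row tibble or list with `tp`, `fp`, `tn`, `fn`.
#' @return One-row tibble: the counts plus `sensitivity`, `specificity`,
#'   `accuracy` (percent) and `mcc`.
#' @export
#' @examples
#' classification_metrics(list(tp = 3, fp = 1, tn = 2, fn = 2))
classification_metrics <- function(counts) {
  tp <- as.numeric(counts$tp); fp <- as.numeric(counts$fp)
  tn <- as.numeric(counts$tn); fn <- as.numeric(counts$fn)
  total <- tp + fp + tn + fn
  if (total <= 0) abort("no predictions to evaluate")
  denom2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  mcc <- if (denom2 == 0) 0 else (tp * tn - fp * fn) / sqrt(denom2)
  tibble::tibble(
    tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_,
    accuracy = 100 * (tp + tn) / total,
    mcc = mcc
  )
}

#' Area under the ROC curve (rank formulation)
#'
#' The probability that a randomly chosen inhibitor receives a higher
#' decision score than a randomly chosen non-inhibitor, with ties counted
#' one half — the Mann–Whitney statistic divided by the number of
#' inhibitor/non-inhibitor pairs.
#'
#' @param scores Numeric decision scores (higher = more inhibitor-like).
#' @param truth Labels aligned with `scores`.
#' @return AUROC in \[0, 1\], or `NA` with a warning when only one class is
#'   present.
#' @export
#' @examples
#' auroc(c(0.9, 0.4, 0.8, 0.1),
#'       c("inhibitor", "inhibitor", "non_inhibitor", "non_inhibitor"))
auroc <- function(scores, truth) {
  assert_labels(truth)
  pos <- truth == "inhibitor"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    warn("AUROC undefined: only one class present")
    return(NA_real_)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
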