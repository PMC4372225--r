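#' Signed sum-score classifier
#'
#' The interpretable best-fingerprint rule: a compound's score is the
#' number of selected positive bits it sets minus the number of selected
#' negative bits it sets, and it is predicted an inhibitor when the score
#' reaches the decision threshold. With the default threshold 1, a score
#' of 0 (equally many positive and negative bits) is classified
#' non-inhibitor. All bits carry unit weight.
#'
#' @param positive Character vector of positive descriptor names (+1 each
#'   when present), or a `selected_fingerprints` object from which both
#'   lists are taken.
#' @param negative Character vector of negative descriptor names (−1 each).
#' @param threshold Integer decision threshold `t`: predict inhibitor iff
#'   score ≥ `t`. Default 1; raise it for higher specificity, lower it for
#'   higher sensitivity.
#' @return A `sum_score_model`.
#' @export
#' @examples
#' m <- sum_score_model(c("FP1", "FP2"), c("FP3"), threshold = 1)
#' fp <- tibble::tibble(compound_id = "x", FP1 = 1L, FP2 = 0L, FP3 = 1L)
#' predict(m, fp)
sum_score_model <- function(positive, negative = NULL, threshold = 1L) {
  if (inherits(positive, "selected_fingerprints")) {
    negative <- positive$negative
    positive <- positive$positive
  }
  positive <- as.character(positive)
  negative <- as.character(negative)
  if (length(intersect(positive, negative)) > 0) {
    abort("positive and negative descriptor lists must be disjoint")
  }
  if (threshold != floor(threshold)) abort("threshold must be an integer")
  structure(
    list(positive = positive, negative = negative,
         threshold = as.integer(threshold)),
    class = "sum_score_model"
  )
}

#' @export
print.sum_score_model <- function(x, ...) {
  cat(sprintf("<sum_score_model> +%d/-%d bits, predict inhibitor iff score >= %d\n",
              length(x$positive), length(x$negative), x$threshold))
  invisible(x)
}

#' Compute sum scores for a fingerprint matrix
#'
#' @param model A [sum_score_model()].
#' @param fp Fingerprint tibble containing every descriptor the model
#'   names; a missing descriptor is an error naming it.
#' @return Tibble `compound_id`, `score` (integer in
#'   \[−|negative|, +|positive|\]).
#' @export
sum_scores <- function(model, fp) {
  stopifnot(inherits(model, "sum_score_model"))
  need <- c(model$positive, model$negative)
  missing <- setdiff(need, names(fp))
  if (length(missing) > 0) {
    abort(sprintf("fingerprint matrix lacks model descriptor(s): %s",
                  paste(sQuote(missing), collapse = ", ")))
  }
  m <- fp_as_matrix(fp[c("compound_id", need)])
  pos <- if (length(model$positive)) {
    rowSums(m[, model$positive, drop = FALSE])
  } else 0L
  neg <- if (length(model$negative)) {
    rowSums(m[, model$negative, drop = FALSE])
  } else 0L
  tibble::tibble(compound_id = fp$compound_id,
                 score = as.integer(pos - neg))
}

#' Predict labels with a sum-score model
#'
#' @param object A [sum_score_model()].
#' @param fingerprints Fingerprint tibble.
#' @param ... Unused.
#' @return Tibble `compound_id`, `score`, `prediction`.
#' @export
predict.sum_score_model <- function(object, fingerprints, ...) {
  sc <- sum_scores(object, fingerprints)
  sc$prediction <- ifelse(sc$score >= object$threshold,
                          "inhibitor", "non_inhibitor")
  sc
}

#' Sweep the sum-score decision threshold
#'
#' Evaluates the model at every integer threshold from the minimum observed
#' score to one past the maximum, so both degenerate endpoints
#' (everything predicted inhibitor; nothing predicted inhibitor) appear.
#' Sensitivity is non-increasing and specificity non-decreasing along the
#' sweep.
#'
#' @param model A [sum_score_model()] (its own threshold is ignored).
#' @param fp Fingerprint tibble.
#' @param dataset Activity dataset (or label vector) aligned by
#'   `compound_id`.
#' @return Tibble with one row per threshold: `threshold`, confusion
#'   counts, `sensitivity`, `specificity`, `accuracy`, `mcc`; classed
#'   `fs_sweep` for [autoplot()].
#' @export
threshold_sweep <- function(model, fp, dataset) {
  labels <- resolve_labels(fp, dataset)
  assert_labels(labels)
  if (length(unique(labels)) < 2L) {
    abort("threshold sweep needs both label classes present")
  }
  sc <- sum_scores(model, fp)$score
  ts <- seq.int(min(sc), max(sc) + 1L)
  rows <- lapply(ts, function(t) {
    pred <- ifelse(sc >= t, "inhibitor", "non_inhibitor")
    cc <- confusion_counts(labels, pred)
    dplyr::bind_cols(tibble::tibble(threshold = t),
                     classification_metrics(cc))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("fs_sweep", class(out))
  out
}
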