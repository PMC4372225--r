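#' Per-class fingerprint frequencies
#'
#' For every binary descriptor, computes its percent frequency among
#' inhibitors and among non-inhibitors:
#' \deqn{F_i^A = \frac{\sum_{j=1}^{N_A} D_i^j}{N_A} \times 100, \qquad
#'       F_i^I = \frac{\sum_{j=1}^{N_I} D_i^j}{N_I} \times 100}
#' where \eqn{D_i^j \in \{0,1\}} is the value of descriptor *i* for
#' molecule *j* and \eqn{N_A}, \eqn{N_I} are the class sizes. Frequencies
#' are kept at full precision; round only for display.
#'
#' @param fp Fingerprint tibble (`compound_id` + 0/1 columns).
#' @param dataset Activity dataset supplying labels, matched by
#'   `compound_id`; alternatively a character vector of labels aligned to
#'   the fingerprint rows.
#' @return Tibble with one row per descriptor: `descriptor`, `freq_active`,
#'   `freq_inactive`.
#' @export
#' @examples
#' fp <- tibble::tibble(compound_id = c("a", "b", "c"),
#'                      FP1 = c(1L, 0L, 1L), FP2 = c(0L, 0L, 0L))
#' labs <- c("inhibitor", "inhibitor", "non_inhibitor")
#' fingerprint_frequencies(fp, labs)
fingerprint_frequencies <- function(fp, dataset) {
  labels <- resolve_labels(fp, dataset)
  assert_labels(labels)
  n_a <- sum(labels == "inhibitor")
  n_i <- sum(labels == "non_inhibitor")
  if (n_a == 0L || n_i == 0L) {
    abort("undefined frequency: both label classes must be non-empty")
  }
  m <- fp_as_matrix(fp)
  tibble::tibble(
    descriptor = colnames(m),
    freq_active = unname(colSums(m[labels == "inhibitor", , drop = FALSE])) / n_a * 100,
    freq_inactive = unname(colSums(m[labels == "non_inhibitor", , drop = FALSE])) / n_i * 100
  )
}

resolve_labels <- function(fp, dataset) {
  if (is.character(dataset) || is.factor(dataset)) {
    labels <- as.character(dataset)
    if (length(labels) != nrow(fp)) {
      abort("label vector length must match the number of fingerprint rows")
    }
    return(labels)
  }
  stopifnot(all(c("compound_id", "label") %in% names(dataset)))
  pos <- match(fp$compound_id, dataset$compound_id)
  if (anyNA(pos)) abort("fingerprint rows without a label in the dataset")
  as.character(dataset$label[pos])
}

#' Fingerprint score (class-frequency difference)
#'
#' Adds the fingerprint score \eqn{FS_i = F_i^A - F_i^I} to a frequency
#' table. A positive score means the bit is more frequent in inhibitors; a
#' negative score means it is preferred in non-inhibitors. The magnitude
#' ranks the bit's discriminative value.
#'
#' @param freq_table Output of [fingerprint_frequencies()] (or any tibble
#'   with `freq_active` and `freq_inactive` columns, e.g. a published
#'   frequency table).
#' @return The table with a `score` column, classed for [autoplot()].
#' @export
fingerprint_scores <- function(freq_table) {
  stopifnot(all(c("freq_active", "freq_inactive") %in% names(freq_table)))
  out <- dplyr::mutate(tibble::as_tibble(freq_table),
                       score = .data$freq_active - .data$freq_inactive)
  class(out) <- c("fp_score_table", class(out))
  out
}

#' Score all fingerprints of a dataset
#'
#' Convenience composition of [fingerprint_frequencies()] and
#' [fingerprint_scores()].
#'
#' @inheritParams fingerprint_frequencies
#' @return Score table (`descriptor`, `freq_active`, `freq_inactive`,
#'   `score`).
#' @export
score_fingerprints <- function(fp, dataset) {
  fingerprint_scores(fingerprint_frequencies(fp, dataset))
}

#' Remove redundant fingerprints by phi correlation
#'
#' Drops zero-variance descriptors, then scans the remaining columns in
#' index order, keeping a column only if its absolute phi coefficient
#' (Pearson correlation between 0/1 columns) with every previously kept
#' column is at most `threshold`. The scan order makes the filter
#' deterministic and independent of any scoring, matching a
#' redundancy-first, score-second selection protocol. Idempotent.
#'
#' @param fp Fingerprint tibble.
#' @param threshold Correlation threshold in (0, 1]; default 0.6.
#' @return Filtered fingerprint tibble with attribute `removal_log`, a
#'   tibble naming each dropped descriptor and the kept descriptor that
#'   blocked it (`NA` for zero-variance drops).
#' @export
filter_redundant <- function(fp, threshold = 0.6) {
  assert_scalar_number(threshold, "threshold", lower = 0, upper = 1,
                       strict_lower = TRUE)
  m <- fp_as_matrix(fp)
  if (ncol(m) == 0L) abort("fingerprint matrix has no descriptor columns")
  v <- apply(m, 2, function(col) length(unique(col)) > 1L)
  log <- tibble::tibble(
    descriptor = colnames(m)[!v],
    reason = rep("zero_variance", sum(!v)),
    blocked_by = rep(NA_character_, sum(!v))
  )
  m2 <- m[, v, drop = FALSE]
  kept <- integer(0)
  if (ncol(m2) > 0) {
    cc <- abs(suppressWarnings(cor(m2)))
    for (j in seq_len(ncol(m2))) {
      blockers <- kept[cc[kept, j] > threshold]
      if (length(blockers) == 0L) {
        kept <- c(kept, j)
      } else {
        log <- dplyr::bind_rows(log, tibble::tibble(
          descriptor = colnames(m2)[j],
          reason = "correlated",
          blocked_by = colnames(m2)[blockers[1]]
        ))
      }
    }
  }
  keep_names <- colnames(m2)[kept]
  out <- fp[c("compound_id", keep_names)]
  attr(out, "removal_log") <- log
  attr(out, "correlation_threshold") <- threshold
  out
}

#' Select the best positive and negative fingerprints
#'
#' Takes the `k_pos` highest-scoring bits with strictly positive score
#' (descending) and the `k_neg` lowest-scoring bits with strictly negative
#' score (ascending). Ties are broken by the descriptor's position in the
#' score table, i.e. by descriptor index. Fewer bits are returned when
#' fewer qualify. Selection should always be computed on the training data
#' only; held-out compounds must not influence it.
#'
#' @param score_table Score table from [score_fingerprints()], typically
#'   computed on a redundancy-filtered matrix.
#' @param k_pos,k_neg Number of positive / negative bits to keep
#'   (default 10 each).
#' @return A `selected_fingerprints` object: ordered character vectors
#'   `$positive` and `$negative`, the selected `$table` rows, and
#'   `$provenance`.
#' @export
select_best_fingerprints <- function(score_table, k_pos = 10, k_neg = 10) {
  k_pos <- assert_count(k_pos, "k_pos")
  k_neg <- assert_count(k_neg, "k_neg")
  stopifnot(all(c("descriptor", "score") %in% names(score_table)))
  idx <- seq_len(nrow(score_table))
  pos_rows <- idx[score_table$score > 0]
  pos_rows <- pos_rows[order(-score_table$score[pos_rows], pos_rows)]
  pos_rows <- head(pos_rows, k_pos)
  neg_rows <- idx[score_table$score < 0]
  neg_rows <- neg_rows[order(score_table$score[neg_rows], neg_rows)]
  neg_rows <- head(neg_rows, k_neg)
  structure(
    list(
      positive = score_table$descriptor[pos_rows],
      negative = score_table$descriptor[neg_rows],
      table = tibble::as_tibble(score_table[c(pos_rows, neg_rows), ]),
      provenance = list(
        n_scored = nrow(score_table),
        k_pos = k_pos, k_neg = k_neg
      )
    ),
    class = "selected_fingerprints"
  )
}

#' @export
print.selected_fingerprints <- function(x, ...) {
  cat(sprintf("<selected_fingerprints> %d positive, %d negative (of %d scored)\n",
              length(x$positive), length(x$negative), x$provenance$n_scored))
  cat("  positive:", paste(x$positive, collapse = " "), "\n")
  cat("  negative:", paste(x$negative, collapse = " "), "\n")
  invisible(x)
}

#' Full training-set fingerprint selection
#'
#' The complete selection protocol on one training set: redundancy filter
#' at `threshold`, frequency scoring, then best `k_pos` + `k_neg` pick.
#'
#' @inheritParams fingerprint_frequencies
#' @inheritParams filter_redundant
#' @inheritParams select_best_fingerprints
#' @return `selected_fingerprints` whose provenance records the filter
#'   counts (`n_before_filter`, `n_after_filter`, `correlation_threshold`).
#' @export
select_fingerprints <- function(fp, dataset, threshold = 0.6,
                                k_pos = 10, k_neg = 10) {
  filtered <- filter_redundant(fp, threshold)
  sel <- select_best_fingerprints(score_fingerprints(filtered, dataset),
                                  k_pos = k_pos, k_neg = k_neg)
  sel$provenance$n_before_filter <- ncol(fp) - 1L
  sel$provenance$n_after_filter <- ncol(filtered) - 1L
  sel$provenance$correlation_threshold <- threshold
  sel
}
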