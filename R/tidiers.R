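#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a cross-validation result into per-fold rows
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return Tibble with one row per fold per repeat.
#' @export
tidy.cv_result <- function(x, ...) tibble::as_tibble(x$folds)

#' One-row summary of a cross-validation result
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return One-row tibble of macro-averaged metrics with protocol columns.
#' @export
glance.cv_result <- function(x, ...) {
  dplyr::bind_cols(
    tibble::as_tibble(x$summary),
    tibble::tibble(learner = x$spec$learner$name,
                   k = x$spec$k, repeats = x$spec$repeats)
  )
}

#' Tidy a fingerprint selection
#'
#' @param x A `selected_fingerprints` object.
#' @param ... Unused.
#' @return The selected score-table rows with a `direction` column, in
#'   selection order (positives descending, then negatives ascending).
#' @export
tidy.selected_fingerprints <- function(x, ...) {
  tab <- tibble::as_tibble(x$table)
  tab$direction <- rep(c("positive", "negative"),
                       c(length(x$positive), length(x$negative)))
  tab
}

#' Tidy a sum-score model
#'
#' @param x A `sum_score_model`.
#' @param ... Unused.
#' @return Tibble `descriptor`, `weight` (+1 / −1).
#' @export
tidy.sum_score_model <- function(x, ...) {
  tibble::tibble(
    descriptor = c(x$positive, x$negative),
    weight = rep(c(1L, -1L), c(length(x$positive), length(x$negative)))
  )
}
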