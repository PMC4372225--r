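#' Plot a sum-score threshold sweep
#'
#' Sensitivity, specificity and accuracy (percent, left axis) with MCC on
#' a secondary axis, against the integer decision threshold — the
#' trade-off view used to pick the balance point of the sum-score rule.
#'
#' @param object An `fs_sweep` from [threshold_sweep()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fs_sweep <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object),
    c("sensitivity", "specificity", "accuracy"),
    names_to = "metric", values_to = "percent"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$percent, colour = .data$metric)) +
    ggplot2::geom_line(
      data = tibble::as_tibble(object),
      ggplot2::aes(y = .data$mcc * 100, linetype = "MCC"),
      colour = "grey25"
    ) +
    ggplot2::scale_y_continuous(
      "percent",
      sec.axis = ggplot2::sec_axis(~ . / 100, name = "MCC")
    ) +
    ggplot2::scale_linetype_manual(NULL, values = c(MCC = "dashed")) +
    ggplot2::labs(x = "decision threshold (summed best fingerprints)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a fingerprint score table
#'
#' Signed class-frequency differences of the top-ranking bits, positives
#' up, negatives down.
#'
#' @param object An `fp_score_table` from [score_fingerprints()].
#' @param top_n Bits shown from each end of the ranking (default 10).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fp_score_table <- function(object, top_n = 10, ...) {
  tab <- tibble::as_tibble(object)
  tab <- dplyr::arrange(tab, dplyr::desc(.data$score))
  shown <- dplyr::bind_rows(head(tab, top_n), utils::tail(tab, top_n))
  shown <- dplyr::distinct(shown, .data$descriptor, .keep_all = TRUE)
  shown$descriptor <- factor(shown$descriptor, levels = rev(shown$descriptor))
  ggplot2::ggplot(shown,
                  ggplot2::aes(x = .data$score, y = .data$descriptor,
                               fill = .data$score > 0)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = "fingerprint score (freq. in inhibitors − non-inhibitors, %)",
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-fold cross-validation metrics
#'
#' @param object A `cv_result`.
#' @param ... Unused.
#' @return A ggplot object with one box per metric over the folds.
#' @export
autoplot.cv_result <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tidy(object),
    c("sensitivity", "specificity", "accuracy"),
    names_to = "metric", values_to = "percent"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$percent)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "percent (per fold)") +
    ggplot2::theme_minimal()
}

#' Plot a functional-group frequency profile
#'
#' Mean per-molecule count of each functional group by activity class,
#' with ±1 standard deviation bars.
#'
#' @param object An `fg_profile` from [functional_group_profile()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fg_profile <- function(object, ...) {
  tab <- tibble::as_tibble(object)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$group, y = .data$mean,
                                    fill = .data$label)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.9)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(width = 0.9), width = 0.25
    ) +
    ggplot2::labs(x = NULL, y = "mean count per molecule", fill = NULL) +
    ggplot2::theme_minimal()
}
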