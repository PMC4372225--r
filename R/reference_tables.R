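#' Published best-20 fingerprint frequency table (EGFR10 benchmark)
#'
#' The published selection of the 10 most inhibitor-enriched and 10 most
#' non-inhibitor-enriched PubChem bits on the EGFR10 benchmark (508
#' inhibitors at IC50 < 10 nM vs 2997 non-inhibitors), with their percent
#' frequencies in each class and the printed frequency difference. Ships
#' as a plain-CSV fixture; useful as a worked example for
#' [fingerprint_scores()] and [select_best_fingerprints()] and as the
#' default bit lists of a ready-made [sum_score_model()].
#'
#' Two printed differences (FP815: 15.99, FP145: −14.96) disagree with the
#' rounded frequency columns by 0.01 — an artifact of the source table
#' rounding unrounded frequencies; scores recomputed from the two rounded
#' frequency columns give 16.00 and −14.97.
#'
#' @return Tibble `descriptor`, `freq_active`, `freq_inactive`,
#'   `difference`, `direction`, in the published order.
#' @export
#' @examples
#' tab <- egfr10_best20()
#' fingerprint_scores(tab)
egfr10_best20 <- function() {
  path <- system.file("extdata", "egfr10_best20_fingerprints.csv",
                      package = "fpqsar", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
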