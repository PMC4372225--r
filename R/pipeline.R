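#' Configure a full pipeline run
#'
#' Bundles every knob of the workflow with defaults that reproduce the
#' reference protocol: IC50 cutoff 10 nM, 90/10 stratified split, phi
#' correlation filter at 0.6, best 10 + 10 fingerprints, sum-score decision
#' threshold 1, and a 100-tree random forest evaluated by stratified
#' five-fold cross-validation repeated five times.
#'
#' @param activities Path to the activity table (CSV/TSV).
#' @param fingerprints Path to the PaDEL-dialect fingerprint CSV.
#' @param output_dir Directory the run writes into.
#' @param cutoff_nm IC50 cutoff (nM).
#' @param validation_fraction Held-out fraction of the 90/10-style split.
#' @param correlation_threshold Redundancy filter threshold.
#' @param k_pos,k_neg Selection sizes.
#' @param decision_threshold Sum-score decision threshold.
#' @param learner A [learner_spec()].
#' @param cv_k,cv_repeats Cross-validation folds and repeats.
#' @param classes Scaffold classes for the experiment grid (empty to skip).
#' @param registry Scaffold-class registry.
#' @param seed Master seed; all stage seeds derive from it.
#' @return A `run_config` list.
#' @export
run_config <- function(activities, fingerprints, output_dir,
                       cutoff_nm = 10, validation_fraction = 0.1,
                       correlation_threshold = 0.6, k_pos = 10, k_neg = 10,
                       decision_threshold = 1,
                       learner = learner_spec("random_forest"),
                       cv_k = 5, cv_repeats = 5,
                       classes = character(0),
                       registry = scaffold_registry(),
                       seed = 1L) {
  structure(
    list(activities = activities, fingerprints = fingerprints,
         output_dir = output_dir, cutoff_nm = cutoff_nm,
         validation_fraction = validation_fraction,
         correlation_threshold = correlation_threshold,
         k_pos = k_pos, k_neg = k_neg,
         decision_threshold = decision_threshold,
         learner = learner, cv_k = cv_k, cv_repeats = cv_repeats,
         classes = classes, registry = registry, seed = as.integer(seed)),
    class = "run_config"
  )
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  })
}

#' Run the complete classification pipeline
#'
#' Executes dataset construction, the train/validation split,
#' redundancy-filtered frequency selection on the training set, the
#' sum-score threshold sweep, cross-validated learner evaluation and the
#' validation report, writing every intermediate plus a machine-readable
#' `manifest.json` into `config$output_dir`. Rerunning with the same
#' config and inputs reproduces the outputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$output_dir, ...)

  records <- stage("activity load",
                   read_activity_table(config$activities, validate_smiles = FALSE))
  ds <- stage("dataset build", build_activity_dataset(records, config$cutoff_nm))
  fp <- stage("fingerprint load", {
    fp0 <- read_fingerprint_matrix(config$fingerprints)
    align_fingerprints(fp0, ds)
  })

  split <- stage("split", split_train_validation(
    ds, config$validation_fraction, seed = child_seed(config$seed, 1L)))
  fp_train <- align_fingerprints(fp, split$train)

  sel <- stage("selection", select_fingerprints(
    fp_train, split$train, threshold = config$correlation_threshold,
    k_pos = config$k_pos, k_neg = config$k_neg))
  scores <- stage("scoring",
                  score_fingerprints(fp_train, split$train))
  model <- sum_score_model(sel, threshold = config$decision_threshold)
  sweep <- stage("threshold sweep", threshold_sweep(model, fp_train, split$train))

  cv <- stage("cross-validation", cross_validate(
    split$train, fp, config$learner, k = config$cv_k,
    repeats = config$cv_repeats, seed = child_seed(config$seed, 2L),
    tag = "train CV"))
  val_report <- stage("validation", train_and_test(
    split$train, split$validation, fp, learner = config$learner,
    tag = "trained-on-train tested-on-validation"))
  sum_val <- stage("sum-score validation", {
    pred <- predict(model, align_fingerprints(fp, split$validation))
    evaluate_predictions(as.character(split$validation$label),
                         pred$prediction, pred$score,
                         "sum-score tested-on-validation")
  })
  reports <- dplyr::bind_rows(cv$summary, val_report, sum_val)

  # ---- write artifacts --------------------------------------------------
  readr::write_csv(tibble::as_tibble(ds), out("dataset.csv"), progress = FALSE)
  manifest_split <- dplyr::bind_rows(
    dplyr::mutate(tibble::as_tibble(split$train), split = "train"),
    dplyr::mutate(tibble::as_tibble(split$validation), split = "validation")
  )
  readr::write_csv(manifest_split, out("split.csv"), progress = FALSE)
  readr::write_tsv(
    dplyr::arrange(tibble::as_tibble(scores), dplyr::desc(.data$score)),
    out("score_table.tsv"), progress = FALSE
  )
  jsonlite::write_json(
    list(positive = sel$positive, negative = sel$negative,
         threshold = config$decision_threshold),
    out("selected.json"), auto_unbox = TRUE, pretty = TRUE
  )
  readr::write_tsv(tibble::as_tibble(sweep), out("sweep.tsv"), progress = FALSE)
  report_cols <- c("experiment", "sensitivity", "specificity", "accuracy",
                   "mcc", "auroc")
  readr::write_tsv(reports[report_cols], out("reports.tsv"), progress = FALSE)

  manifest <- list(
    parameters = list(
      cutoff_nm = config$cutoff_nm,
      validation_fraction = config$validation_fraction,
      correlation_threshold = config$correlation_threshold,
      k_pos = config$k_pos, k_neg = config$k_neg,
      decision_threshold = config$decision_threshold,
      learner = config$learner$name,
      hyperparameters = config$learner$hyperparameters,
      cv_k = config$cv_k, cv_repeats = config$cv_repeats,
      seed = config$seed
    ),
    dataset = as.list(dataset_summary(ds)),
    selection = list(
      positive = sel$positive, negative = sel$negative,
      n_before_filter = sel$provenance$n_before_filter,
      n_after_filter = sel$provenance$n_after_filter
    ),
    reports = lapply(seq_len(nrow(reports)), function(i) as.list(reports[i, ])),
    versions = list(
      fpqsar = as.character(utils::packageVersion("fpqsar")),
      r = as.character(getRversion())
    )
  )
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
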