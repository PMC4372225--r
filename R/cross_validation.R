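#' Stratified fold assignment
#'
#' Assigns each compound to one of `k` folds, separately within each label
#' class so every fold sees (nearly) the class proportions of the whole
#' set. Deterministic given `seed`.
#'
#' @param labels Character vector of labels.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1:k`.
#' @export
make_stratified_folds <- function(labels, k = 5, seed = NULL) {
  k <- assert_count(k, "k", lower = 2L)
  counts <- table(labels)
  if (any(counts < k)) {
    abort(sprintf("every class needs at least k = %d members for %d-fold CV", k, k))
  }
  folds <- integer(length(labels))
  with_seed(seed, {
    for (lab in names(counts)) {
      idx <- which(labels == lab)
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}

evaluate_predictions <- function(truth, prediction, scores, tag) {
  rep <- classification_metrics(confusion_counts(truth, prediction))
  rep$auroc <- if (length(unique(truth)) == 2L) auroc(scores, truth) else NA_real_
  dplyr::bind_cols(tibble::tibble(experiment = tag), rep)
}

#' Repeated stratified k-fold cross-validation
#'
#' Runs stratified `k`-fold cross-validation `repeats` times with
#' different fold assignments, fitting the learner afresh on each training
#' part (for the `sum_score` learner this re-runs fingerprint selection on
#' the training folds only, so held-out compounds never influence
#' selection). Metrics are computed per fold and macro-averaged over all
#' `k * repeats` folds.
#'
#' @param ds Activity dataset.
#' @param fp Fingerprint tibble covering `ds`.
#' @param learner A [learner_spec()].
#' @param k Folds per repeat (default 5).
#' @param repeats Number of repeats (default 5).
#' @param seed Integer seed; fold assignments and learner fits derive from
#'   it, so the whole run is reproducible.
#' @param tag Experiment tag recorded in the reports.
#' @return A `cv_result` with `$summary` (one-row averaged report),
#'   `$folds` (per-fold reports) and `$spec`.
#' @export
cross_validate <- function(ds, fp, learner, k = 5, repeats = 5, seed = NULL,
                           tag = "cross-validation") {
  repeats <- assert_count(repeats, "repeats", lower = 1L)
  fp <- align_fingerprints(fp, ds)
  labels <- as.character(ds$label)

  fold_rows <- list()
  for (r in seq_len(repeats)) {
    folds <- make_stratified_folds(labels, k = k, seed = child_seed(seed, r))
    for (f in seq_len(k)) {
      test_idx <- which(folds == f)
      train_idx <- which(folds != f)
      spec_f <- learner
      spec_f$seed <- child_seed(seed, 1000L * r + f)
      fit <- fit_learner(spec_f,
                         fp[train_idx, , drop = FALSE],
                         rebuild_subset(ds, train_idx))
      pred <- predict(fit, fp[test_idx, , drop = FALSE])
      rep_row <- evaluate_predictions(labels[test_idx], pred$prediction,
                                      pred$score, tag)
      fold_rows[[length(fold_rows) + 1L]] <-
        dplyr::bind_cols(tibble::tibble(repeat_id = r, fold = f), rep_row)
    }
  }
  folds_tbl <- dplyr::bind_rows(fold_rows)
  metric_cols <- c("sensitivity", "specificity", "accuracy", "mcc", "auroc")
  summary <- folds_tbl %>%
    dplyr::summarise(
      experiment = tag,
      dplyr::across(dplyr::all_of(c("tp", "fp", "tn", "fn")), sum),
      dplyr::across(dplyr::all_of(metric_cols), ~ mean(.x, na.rm = TRUE))
    )
  structure(list(summary = summary, folds = folds_tbl,
                 spec = list(learner = learner, k = k, repeats = repeats,
                             seed = seed)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<cv_result> %s | %s, %d-fold x %d repeats\n",
              s$experiment, x$spec$learner$name, x$spec$k, x$spec$repeats))
  cat(sprintf("  sens %.2f%% | spec %.2f%% | acc %.2f%% | MCC %.3f | AUROC %.3f\n",
              s$sensitivity, s$specificity, s$accuracy, s$mcc, s$auroc))
  invisible(x)
}

#' Train on one dataset, test on another
#'
#' Fits the learner on the training dataset and reports performance on a
#' disjoint test dataset — the design behind cross-class and
#' leave-class-out generalization experiments. The two fingerprint tables
#' must carry identical descriptor columns in identical order.
#'
#' @param train_ds,test_ds Disjoint activity datasets.
#' @param fp_train,fp_test Fingerprint tibbles for the two datasets (pass
#'   one table for both if it covers the union).
#' @param learner A [learner_spec()].
#' @param tag Experiment tag; defaults to "trained-on-X tested-on-Y" built
#'   from the datasets' split tags.
#' @return One-row evaluation report tibble.
#' @export
train_and_test <- function(train_ds, test_ds, fp_train, fp_test = fp_train,
                           learner = learner_spec("random_forest"),
                           tag = NULL) {
  overlap <- intersect(train_ds$compound_id, test_ds$compound_id)
  if (length(overlap) > 0) {
    abort(sprintf("train and test sets overlap (%d shared compounds)",
                  length(overlap)))
  }
  if (!identical(setdiff(names(fp_train), "compound_id"),
                 setdiff(names(fp_test), "compound_id"))) {
    abort("train and test fingerprint tables must have identical descriptor columns")
  }
  fp_tr <- align_fingerprints(fp_train, train_ds)
  fp_te <- align_fingerprints(fp_test, test_ds)
  fit <- fit_learner(learner, fp_tr, train_ds)
  pred <- predict(fit, fp_te)
  if (is.null(tag)) {
    tag <- sprintf("trained-on-%s tested-on-%s",
                   attr(train_ds, "split_tag") %||% "train",
                   attr(test_ds, "split_tag") %||% "test")
  }
  evaluate_predictions(as.character(test_ds$label), pred$prediction,
                       pred$score, tag)
}

#' Run the full class-generalization experiment grid
#'
#' Reproduces the standard experiment matrix around a labeled dataset with
#' scaffold classes: repeated CV on the training split and a validation
#' report, then for every listed class (i) CV on the class subset, (ii)
#' train on that class / test on each other class, (iii) CV on the
#' leave-class-out complement and (iv) train on the complement / test on
#' the held-out class. With two classes this yields the familiar
#' ten-experiment table.
#'
#' @param ds Activity dataset carrying a `scaffold_class` column (see
#'   [annotate_scaffold_class()]) when `classes` is non-empty.
#' @param fp Fingerprint tibble covering `ds`.
#' @param learner A [learner_spec()].
#' @param classes Character vector of scaffold classes to iterate over;
#'   empty for just the CV + validation pair.
#' @param validation_fraction,k,repeats,seed Protocol parameters, see
#'   [split_train_validation()] and [cross_validate()].
#' @return Tibble of evaluation reports, one row per experiment.
#' @export
experiment_matrix <- function(ds, fp, learner = learner_spec("random_forest"),
                              classes = character(0),
                              validation_fraction = 0.1, k = 5, repeats = 5,
                              seed = NULL) {
  split <- split_train_validation(ds, validation_fraction,
                                  seed = child_seed(seed, 1L))
  reports <- list()
  cv_full <- cross_validate(split$train, fp, learner, k = k, repeats = repeats,
                            seed = child_seed(seed, 2L), tag = "train CV")
  reports[["train CV"]] <- cv_full$summary
  reports[["validation"]] <- train_and_test(
    split$train, split$validation, fp, learner = learner,
    tag = "trained-on-train tested-on-validation"
  )

  if (length(classes) > 0 && !"scaffold_class" %in% names(ds)) {
    abort("class experiments need a scaffold_class column; see annotate_scaffold_class()")
  }
  for (cl in classes) {
    sub <- scaffold_subset(ds, cl)
    comp <- leave_class_out(ds, cl)
    reports[[paste0(cl, " CV")]] <- cross_validate(
      sub, fp, learner, k = k, repeats = repeats,
      seed = child_seed(seed, 10L + match(cl, classes)),
      tag = sprintf("%s CV", cl)
    )$summary
    for (other in setdiff(classes, cl)) {
      reports[[paste(cl, "->", other)]] <- train_and_test(
        sub, scaffold_subset(ds, other), fp, learner = learner,
        tag = sprintf("trained-on-%s tested-on-%s", cl, other)
      )
    }
    reports[[paste0("minus-", cl, " CV")]] <- cross_validate(
      comp, fp, learner, k = k, repeats = repeats,
      seed = child_seed(seed, 20L + match(cl, classes)),
      tag = sprintf("minus-%s CV", cl)
    )$summary
    reports[[paste("minus", cl, "->", cl)]] <- train_and_test(
      comp, sub, fp, learner = learner,
      tag = sprintf("trained-on-minus-%s tested-on-%s", cl, cl)
    )
  }
  dplyr::bind_rows(reports)
}
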