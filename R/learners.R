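#' Specify a classification learner
#'
#' A uniform contract over interchangeable classifiers: every learner can
#' be fitted on a training fingerprint matrix + labels and then produces,
#' for new compounds, a real-valued decision score (higher = more
#' inhibitor-like) and a hard label. Available learners:
#'
#' * `random_forest` — 100 trees by default (`trees`); score is the
#'   inhibitor vote fraction. The default and recommended learner.
#' * `naive_bayes` — Naive Bayes on the binary bits (`laplace` smoothing,
#'   default 1); score is the inhibitor posterior.
#' * `svm` — C-SVC with a radial kernel; score is the decision value.
#' * `knn` — k-nearest neighbour (`k`, default 1); score is the inhibitor
#'   neighbour fraction.
#' * `sum_score` — the interpretable best-fingerprint rule: fitting runs
#'   the full selection protocol (redundancy filter at
#'   `correlation_threshold`, frequency scoring, best `k_pos`/`k_neg`
#'   pick) on the training data only; score is the signed bit sum and the
#'   label uses `decision_threshold` (default 1).
#'
#' @param name Learner name.
#' @param ... Hyperparameters overriding the defaults above.
#' @param seed Integer seed used when fitting (stochastic learners).
#' @return A `learner_spec`.
#' @export
#' @examples
#' learner_spec("random_forest", trees = 100, seed = 7)
learner_spec <- function(name = c("random_forest", "naive_bayes", "svm",
                                  "knn", "sum_score"),
                         ..., seed = NULL) {
  name <- match.arg(name)
  defaults <- switch(name,
    random_forest = list(trees = 100L),
    naive_bayes = list(laplace = 1),
    svm = list(cost = 1),
    knn = list(k = 1L),
    sum_score = list(correlation_threshold = 0.6, k_pos = 10L, k_neg = 10L,
                     decision_threshold = 1L)
  )
  hp <- utils::modifyList(defaults, list(...))
  structure(list(name = name, hyperparameters = hp, seed = seed),
            class = "learner_spec")
}

#' @export
print.learner_spec <- function(x, ...) {
  hp <- paste(names(x$hyperparameters), unlist(x$hyperparameters),
              sep = "=", collapse = ", ")
  cat(sprintf("<learner_spec> %s (%s)\n", x$name, hp))
  invisible(x)
}

#' Fit a learner on a training set
#'
#' @param spec A [learner_spec()].
#' @param fp Fingerprint tibble; rows are aligned to `dataset` by
#'   `compound_id`.
#' @param dataset Activity dataset supplying the training labels.
#' @return A `fitted_learner` usable with [predict_scores()] and
#'   [predict()][predict.fitted_learner].
#' @export
fit_learner <- function(spec, fp, dataset) {
  stopifnot(inherits(spec, "learner_spec"))
  fp <- align_fingerprints(fp, dataset)
  labels <- factor(as.character(dataset$label), levels = label_levels())
  if (any(table(labels) == 0L)) abort("training data must contain both classes")
  hp <- spec$hyperparameters
  x <- fp_as_matrix(fp)

  fit <- with_seed(spec$seed, switch(spec$name,
    random_forest = randomForest::randomForest(
      x = x, y = labels, ntree = hp$trees
    ),
    naive_bayes = e1071::naiveBayes(
      x = as_bit_factors(x), y = labels, laplace = hp$laplace
    ),
    svm = e1071::svm(
      x = x, y = labels, cost = hp$cost, kernel = "radial", scale = FALSE
    ),
    knn = list(train = x, labels = labels, k = hp$k),
    sum_score = sum_score_model_from_training(fp, dataset, hp)
  ))

  structure(list(spec = spec, fit = fit,
                 descriptors = colnames(x)),
            class = "fitted_learner")
}

sum_score_model_from_training <- function(fp, dataset, hp) {
  sel <- select_fingerprints(fp, dataset,
                             threshold = hp$correlation_threshold,
                             k_pos = hp$k_pos, k_neg = hp$k_neg)
  model <- sum_score_model(sel, threshold = hp$decision_threshold)
  model$selection <- sel
  model
}

as_bit_factors <- function(x) {
  as.data.frame(lapply(as.data.frame(x), factor, levels = c("0", "1")))
}

#' Decision scores for new compounds
#'
#' @param object A `fitted_learner`.
#' @param fp Fingerprint tibble with the training descriptor columns.
#' @return Numeric vector of decision scores, one per row of `fp` (higher =
#'   more inhibitor-like).
#' @export
predict_scores <- function(object, fp) {
  stopifnot(inherits(object, "fitted_learner"))
  missing <- setdiff(object$descriptors, names(fp))
  if (length(missing) > 0) {
    abort(sprintf("fingerprint matrix lacks %d training descriptor(s), e.g. %s",
                  length(missing), paste(sQuote(head(missing, 3)), collapse = ", ")))
  }
  x <- fp_as_matrix(fp[c("compound_id", object$descriptors)])
  spec <- object$spec
  switch(spec$name,
    random_forest = unname(predict(object$fit, x, type = "prob")[, "inhibitor"]),
    naive_bayes = unname(predict(object$fit, as_bit_factors(x),
                                 type = "raw")[, "inhibitor"]),
    svm = {
      pr <- predict(object$fit, x, decision.values = TRUE)
      dv <- attr(pr, "decision.values")
      orient <- if (grepl("^inhibitor/", colnames(dv)[1])) 1 else -1
      unname(orient * dv[, 1])
    },
    knn = {
      pr <- class::knn(object$fit$train, x, object$fit$labels,
                       k = object$fit$k, prob = TRUE)
      p <- attr(pr, "prob")
      unname(ifelse(pr == "inhibitor", p, 1 - p))
    },
    sum_score = as.numeric(sum_scores(object$fit, fp)$score)
  )
}

#' Predict activity labels with a fitted learner
#'
#' @param object A `fitted_learner`.
#' @param fingerprints Fingerprint tibble.
#' @param ... Unused.
#' @return Tibble `compound_id`, `score`, `prediction`.
#' @export
predict.fitted_learner <- function(object, fingerprints, ...) {
  sc <- predict_scores(object, fingerprints)
  pred <- switch(object$spec$name,
    sum_score = ifelse(sc >= object$fit$threshold, "inhibitor", "non_inhibitor"),
    random_forest = ,
    naive_bayes = ,
    knn = ifelse(sc > 0.5, "inhibitor", "non_inhibitor"),
    svm = ifelse(sc > 0, "inhibitor", "non_inhibitor")
  )
  tibble::tibble(compound_id = fingerprints$compound_id,
                 score = sc, prediction = pred)
}
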