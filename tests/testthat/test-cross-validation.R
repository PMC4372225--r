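test_that("stratified folds partition compounds and respect class balance", {
  labels <- rep(c("inhibitor", "non_inhibitor"), c(20, 80))
  folds <- make_stratified_folds(labels, k = 5, seed = 4)
  expect_length(folds, 100)
  expect_setequal(unique(folds), 1:5)
  for (f in 1:5) {
    expect_equal(sum(folds == f & labels == "inhibitor"), 4)
    expect_equal(sum(folds == f & labels == "non_inhibitor"), 16)
  }
  expect_identical(folds, make_stratified_folds(labels, k = 5, seed = 4))
  expect_error(make_stratified_folds(rep(c("inhibitor", "non_inhibitor"),
                                         c(3, 50)), k = 5),
               "at least k")
})

test_that("cross-validation is deterministic and covers every compound", {
  sim <- separable_sim(n = 25, seed = 31)
  spec <- learner_spec("sum_score", k_pos = 4, k_neg = 4)
  cv1 <- cross_validate(sim$dataset, sim$fingerprints, spec, k = 5,
                        repeats = 2, seed = 8)
  cv2 <- cross_validate(sim$dataset, sim$fingerprints, spec, k = 5,
                        repeats = 2, seed = 8)
  expect_equal(cv1$summary, cv2$summary)
  expect_equal(nrow(cv1$folds), 10)
  # every compound sits in exactly one test fold per repeat
  per_repeat <- tapply(cv1$folds$tp + cv1$folds$fp +
                         cv1$folds$tn + cv1$folds$fn,
                       cv1$folds$repeat_id, sum)
  expect_true(all(per_repeat == nrow(sim$dataset)))
  expect_s3_class(glance(cv1), "tbl_df")
  expect_s3_class(tidy(cv1), "tbl_df")
  expect_s3_class(autoplot(cv1), "ggplot")
})

test_that("one CV repeat with a deterministic learner equals averaged train/test calls", {
  sim <- separable_sim(n = 25, seed = 37)
  spec <- learner_spec("sum_score", k_pos = 4, k_neg = 4)
  seed <- 14
  cv <- cross_validate(sim$dataset, sim$fingerprints, spec, k = 4,
                       repeats = 1, seed = seed)
  labels <- as.character(sim$dataset$label)
  folds <- make_stratified_folds(labels, k = 4,
                                 seed = fpqsar:::child_seed(seed, 1L))
  manual <- sapply(1:4, function(f) {
    tr <- fpqsar:::rebuild_subset(sim$dataset, which(folds != f))
    te <- fpqsar:::rebuild_subset(sim$dataset, which(folds == f))
    train_and_test(tr, te, sim$fingerprints, learner = spec)$mcc
  })
  expect_equal(cv$summary$mcc, mean(manual))
})

test_that("train_and_test enforces disjointness and matching descriptors", {
  sim <- separable_sim(n = 20, seed = 41)
  sp <- split_train_validation(sim$dataset, 0.25, seed = 2)
  expect_error(train_and_test(sim$dataset, sim$dataset, sim$fingerprints),
               "overlap")
  expect_error(
    train_and_test(sp$train, sp$validation, sim$fingerprints,
                   sim$fingerprints[, 1:10]),
    "identical descriptor"
  )
  rep <- train_and_test(sp$train, sp$validation, sim$fingerprints,
                        learner = learner_spec("random_forest", trees = 30,
                                               seed = 3))
  expect_equal(rep$tp + rep$fp + rep$tn + rep$fn, nrow(sp$validation))
  expect_match(rep$experiment, "validation")
})

test_that("models generalize to a held-out class sharing the planted signal", {
  sim <- generate_synthetic(synthetic_spec(
    n_active = 150, n_inactive = 150, n_descriptors = 120,
    planted_positive = data.frame(index = 1:5, p_active = 0.85, p_inactive = 0.15),
    planted_negative = data.frame(index = 6:10, p_active = 0.15, p_inactive = 0.85),
    background_p = 0.3, seed = 53
  ))
  sim <- add_class_structure(sim, class_fraction = 0.3,
                             class_marker_index = 60, seed = 54)
  train <- leave_class_out(sim$dataset, "classA")
  test <- scaffold_subset(sim$dataset, "classA")
  rep <- train_and_test(train, test, sim$fingerprints,
                        learner = learner_spec("random_forest", trees = 50,
                                               seed = 5))
  expect_gt(rep$mcc, 0)
})

test_that("the experiment grid emits one report per design cell", {
  sim <- generate_synthetic(synthetic_spec(
    n_active = 60, n_inactive = 60, n_descriptors = 50,
    planted_positive = data.frame(index = 1:4, p_active = 0.9, p_inactive = 0.1),
    planted_negative = data.frame(index = 5:8, p_active = 0.1, p_inactive = 0.9),
    background_p = 0.3, seed = 61
  ))
  sim <- add_class_structure(sim, 0.4, class_marker_index = 30,
                             class_name = "classA", seed = 62)
  # a second, disjoint tagged class
  untagged <- sim$dataset$scaffold_class == "other"
  flip <- withr::with_seed(63, runif(sum(untagged)) < 0.5)
  sim$dataset$scaffold_class[which(untagged)[flip]] <- "classB"

  spec <- learner_spec("sum_score", k_pos = 4, k_neg = 4)
  reports <- experiment_matrix(sim$dataset, sim$fingerprints, spec,
                               classes = c("classA", "classB"),
                               k = 3, repeats = 1, seed = 7)
  # 2 base rows + per class: self-CV, cross-test, leave-out CV, leave-out-vs-class
  expect_equal(nrow(reports), 10)
  class_rows <- reports[!reports$experiment %in%
                          c("train CV", "trained-on-train tested-on-validation"), ]
  expect_equal(nrow(class_rows), 8)

  base <- experiment_matrix(sim$dataset, sim$fingerprints, spec,
                            classes = character(0), k = 3, repeats = 1, seed = 7)
  expect_equal(nrow(base), 2)

  # reports survive a JSON round-trip unchanged
  tf <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(reports, tf, digits = NA)
  back <- tibble::as_tibble(jsonlite::read_json(tf, simplifyVector = TRUE))
  expect_equal(back$mcc, reports$mcc)
  expect_identical(back$experiment, reports$experiment)
})
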