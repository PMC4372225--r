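test_that("activity tables load with validation and rejection counting", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("compound_id,smiles,ic50_nm",
               "m1,CCO,5.0",
               "m2,not_a_smiles((,12",
               "m3,c1ccccc1,250"), tf)
  expect_message(tab <- read_activity_table(tf), "rejected 1 of 3")
  expect_equal(nrow(tab), 2L)
  expect_equal(attr(tab, "n_rejected"), 1L)
  expect_identical(tab$ic50_nm, c(5.0, 250))

  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines("compound_id,smiles,ic50_nm", empty)
  expect_error(read_activity_table(empty), "zero valid")
  expect_error(read_activity_table("no/such/file.csv"), "not found")
})

test_that("loose headers and the smi dialect resolve to the canonical columns", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Name,SMILES,IC50", "m1,CCO,5", "m2,CCN,-3"), tf)
  tab <- read_activity_table(tf, validate_smiles = FALSE)
  expect_named(tab, c("compound_id", "smiles", "ic50_nm"))
  expect_equal(nrow(tab), 1L)  # non-positive IC50 rejected

  smi <- withr::local_tempfile(fileext = ".smi")
  act <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("CCO m1", "CCN m2"), smi)
  writeLines(c("compound_id,ic50_nm", "m1,4", "m2,40"), act)
  tab2 <- read_activity_table(smi, dialect = "smi", activities = act,
                              validate_smiles = FALSE)
  expect_equal(tab2$ic50_nm, c(4, 40))
})

test_that("dataset construction labels by cutoff and removes conflicts", {
  ds <- build_activity_dataset(tiny_records(), cutoff_nm = 10)
  # compound "a" has IC50 on both sides of 10 nM -> removed
  expect_false("a" %in% ds$compound_id)
  expect_equal(attr(ds, "n_removed_conflicts"), 1L)
  expect_equal(ds$label[ds$compound_id == "b"], "inhibitor")
  expect_equal(ds$label[ds$compound_id == "c"], "non_inhibitor")

  # repeated measurements on one side collapse to one labeled compound
  recs <- tibble::tibble(compound_id = c("x", "x"), smiles = "CC",
                         ic50_nm = c(200, 300))
  ds2 <- build_activity_dataset(recs, cutoff_nm = 100)
  expect_equal(ds2$label, "non_inhibitor")
  expect_equal(nrow(ds2), 1L)

  # conflict count identity: distinct compounds - surviving compounds
  expect_equal(attr(ds, "n_removed_conflicts"),
               dplyr::n_distinct(tiny_records()$compound_id) - nrow(ds))
})

test_that("an IC50 exactly at the cutoff counts as non-inhibiting, not conflicting", {
  recs <- tibble::tibble(compound_id = c("e", "e"), smiles = "CC",
                         ic50_nm = c(10, 10))
  ds <- build_activity_dataset(recs, cutoff_nm = 10)
  expect_equal(ds$label, "non_inhibitor")
  expect_equal(attr(ds, "n_removed_conflicts"), 0L)
})

test_that("dataset construction is idempotent and errors when all conflict", {
  ds <- build_activity_dataset(tiny_records(), cutoff_nm = 10)
  again <- build_activity_dataset(
    tibble::tibble(compound_id = ds$compound_id, smiles = ds$smiles,
                   ic50_nm = ifelse(ds$label == "inhibitor", 1, 1000)),
    cutoff_nm = 10
  )
  expect_identical(again$label, ds$label)
  expect_equal(attr(again, "n_removed_conflicts"), 0L)

  allconf <- tibble::tibble(compound_id = c("z", "z"), smiles = "C",
                            ic50_nm = c(1, 100))
  expect_error(build_activity_dataset(allconf, 10), "empty dataset")
})

test_that("the stratified split hits per-class counts and is deterministic", {
  n_a <- 508; n_i <- 2997
  ds <- fpqsar:::new_activity_dataset(tibble::tibble(
    compound_id = sprintf("c%04d", seq_len(n_a + n_i)),
    smiles = "C",
    label = rep(c("inhibitor", "non_inhibitor"), c(n_a, n_i))
  ))
  sp <- split_train_validation(ds, 0.1, seed = 3)
  val_counts <- table(sp$validation$label)
  expect_lte(abs(val_counts[["inhibitor"]] - round(0.1 * n_a)), 1)
  expect_lte(abs(val_counts[["non_inhibitor"]] - round(0.1 * n_i)), 1)

  # disjoint union reconstructs the parent
  expect_setequal(c(sp$train$compound_id, sp$validation$compound_id),
                  ds$compound_id)
  expect_length(intersect(sp$train$compound_id, sp$validation$compound_id), 0)

  # labels unchanged downstream of the split
  both <- dplyr::bind_rows(sp$train, sp$validation)
  expect_identical(both$label[match(ds$compound_id, both$compound_id)],
                   ds$label)

  sp2 <- split_train_validation(ds, 0.1, seed = 3)
  expect_identical(sp$validation$compound_id, sp2$validation$compound_id)

  tiny <- fpqsar:::new_activity_dataset(tibble::tibble(
    compound_id = letters[1:4], smiles = "C",
    label = rep(c("inhibitor", "non_inhibitor"), each = 2)
  ))
  sp3 <- split_train_validation(tiny, 0.5, seed = 1)
  expect_equal(unname(table(sp3$validation$label)), c(1L, 1L),
               ignore_attr = TRUE)

  one <- fpqsar:::new_activity_dataset(tibble::tibble(
    compound_id = c("a", "b", "c"), smiles = "C",
    label = c("inhibitor", "non_inhibitor", "non_inhibitor")
  ))
  expect_error(split_train_validation(one, 0.1, seed = 1), "at least 2")
})
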