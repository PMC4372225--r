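test_that("class frequencies match hand counts and handle degenerate bits", {
  fp <- tibble::tibble(
    compound_id = c("a1", "a2", "i1", "i2", "i3"),
    FPa = c(1L, 1L, 0L, 1L, 0L),  # all-ones among actives
    FPz = c(0L, 0L, 0L, 0L, 0L),  # all-zero
    FPm = c(1L, 0L, 1L, 1L, 0L)   # 1/2 active, 2/3 inactive
  )
  labels <- c("inhibitor", "inhibitor", rep("non_inhibitor", 3))
  fr <- fingerprint_frequencies(fp, labels)
  expect_equal(fr$freq_active[fr$descriptor == "FPa"], 100)
  expect_equal(fr$freq_active[fr$descriptor == "FPz"], 0)
  expect_equal(fr$freq_inactive[fr$descriptor == "FPz"], 0)
  expect_equal(fr$freq_active[fr$descriptor == "FPm"], 50)
  expect_equal(fr$freq_inactive[fr$descriptor == "FPm"], 200 / 3)

  expect_error(fingerprint_frequencies(fp, rep("inhibitor", 5)),
               "undefined frequency")
})

test_that("frequencies agree with a brute-force count on random matrices", {
  for (seed in 1:4) {
    fx <- random_fp_fixture(n = 50, p = 50, seed = seed)
    got <- fingerprint_frequencies(fx$fp, fx$labels)
    want <- oracle_frequencies(fx$fp, fx$labels)
    expect_equal(got$freq_active, want$freq_active)
    expect_equal(got$freq_inactive, want$freq_inactive)
    expect_true(all(got$freq_active >= 0 & got$freq_active <= 100))
    # score bounds and antisymmetry under swapping the class labels
    sc <- fingerprint_scores(got)
    expect_true(all(abs(sc$score) <= 100))
    swapped <- ifelse(fx$labels == "inhibitor", "non_inhibitor", "inhibitor")
    sc_swap <- fingerprint_scores(fingerprint_frequencies(fx$fp, swapped))
    expect_equal(sc_swap$score, -sc$score)
  }
})

test_that("fingerprint scores reproduce published frequency differences", {
  # benchmark rows: 71.85/43.64 and 21.26/45.15
  sc <- fingerprint_scores(tibble::tibble(
    descriptor = c("FP380", "FP698", "FPeq"),
    freq_active = c(71.85, 21.26, 33.3),
    freq_inactive = c(43.64, 45.15, 33.3)
  ))
  expect_equal(sc$score, c(28.21, -23.89, 0), tolerance = 1e-12)
  expect_equal(sc$score, sc$freq_active - sc$freq_inactive)
})

test_that("redundancy filter removes duplicates, keeps orthogonal bits, is idempotent", {
  fp <- tibble::tibble(
    compound_id = c("a", "b", "c", "d"),
    FP1 = c(1L, 1L, 0L, 0L),
    FP2 = c(1L, 1L, 0L, 0L),  # identical to FP1: |phi| = 1
    FP3 = c(1L, 0L, 1L, 0L),  # phi(FP1, FP3) = 0 by the 2x2 table
    FP4 = c(1L, 1L, 1L, 1L)   # constant
  )
  expect_equal(oracle_phi(fp$FP1, fp$FP3), 0)
  out <- filter_redundant(fp, 0.6)
  expect_named(out, c("compound_id", "FP1", "FP3"))
  log <- attr(out, "removal_log")
  expect_equal(log$reason[log$descriptor == "FP4"], "zero_variance")
  expect_equal(log$blocked_by[log$descriptor == "FP2"], "FP1")

  twice <- filter_redundant(out, 0.6)
  expect_identical(names(twice), names(out))
  expect_error(filter_redundant(fp, 1.5), "threshold")
})

test_that("no surviving pair exceeds the phi threshold on random matrices", {
  for (seed in 1:5) {
    fx <- random_fp_fixture(n = 50, p = 30, seed = 100 + seed, prob = 0.4)
    fp <- fx$fp
    fp$FPdup <- fp$FP1  # an exact duplicate must always be removed
    out <- filter_redundant(fp, 0.6)
    expect_false("FPdup" %in% names(out))
    m <- as.matrix(out[setdiff(names(out), "compound_id")])
    for (i in seq_len(ncol(m) - 1)) {
      for (j in seq(i + 1, ncol(m))) {
        expect_lte(abs(oracle_phi(m[, i], m[, j])), 0.6)
      }
    }
    again <- filter_redundant(out, 0.6)
    expect_identical(names(again), names(out))
  }
})

test_that("best-fingerprint selection orders, signs and tie-breaks correctly", {
  tab <- egfr10_best20()
  sel <- select_best_fingerprints(fingerprint_scores(tab))
  expect_identical(sel$positive,
                   c("FP380", "FP579", "FP189", "FP388", "FP816",
                     "FP815", "FP374", "FP613", "FP661", "FP348"))
  expect_identical(sel$negative,
                   c("FP698", "FP673", "FP690", "FP700", "FP714",
                     "FP145", "FP701", "FP669", "FP195", "FP382"))
  expect_length(intersect(sel$positive, sel$negative), 0)

  # all-negative table yields an empty positive list
  neg_only <- fingerprint_scores(tibble::tibble(
    descriptor = c("A", "B"), freq_active = c(1, 2), freq_inactive = c(5, 9)
  ))
  sel2 <- select_best_fingerprints(neg_only)
  expect_length(sel2$positive, 0)
  expect_identical(sel2$negative, c("B", "A"))

  # equal scores: earlier descriptor index wins
  tied <- fingerprint_scores(tibble::tibble(
    descriptor = c("X", "Y", "Z"), freq_active = c(30, 30, 10),
    freq_inactive = c(10, 10, 30)
  ))
  sel3 <- select_best_fingerprints(tied, k_pos = 1, k_neg = 1)
  expect_identical(sel3$positive, "X")

  # stability: selecting from its own output returns the same sets
  sel4 <- select_best_fingerprints(fingerprint_scores(sel$table))
  expect_identical(sel4$positive, sel$positive)
  expect_identical(sel4$negative, sel$negative)
})

test_that("planted discriminative bits rise to the top of the score ranking", {
  sim <- generate_synthetic(synthetic_spec(
    n_active = 500, n_inactive = 500, n_descriptors = 200,
    planted_positive = data.frame(index = 1:5, p_active = 0.7, p_inactive = 0.4),
    planted_negative = data.frame(index = 6:10, p_active = 0.4, p_inactive = 0.7),
    background_p = 0.3, seed = 42
  ))
  sc <- score_fingerprints(sim$fingerprints, sim$dataset)
  top_pos <- sc$descriptor[order(-sc$score)][1:5]
  top_neg <- sc$descriptor[order(sc$score)][1:5]
  expect_setequal(top_pos, paste0("FP", 1:5))
  expect_setequal(top_neg, paste0("FP", 6:10))
})
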