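#' Specify a synthetic fingerprint benchmark
#'
#' Describes a class-conditional Bernoulli fingerprint benchmark: every
#' descriptor bit of every compound is drawn independently with a
#' class-specific probability. Most bits are background noise (probability
#' `background_p` in both classes); *planted* bits differ between classes
#' and are the signal the selection and classification pipeline should
#' recover. Optional near-duplicate copies of planted bits exercise the
#' redundancy filter. Defaults mirror the scale of a 10 nM kinase
#' inhibitor benchmark: 508 inhibitors vs 2997 non-inhibitors over 881
#' bits.
#'
#' @param n_active,n_inactive Class sizes (defaults 508 / 2997).
#' @param n_descriptors Number of fingerprint bits (default 881).
#' @param planted_positive Tibble/data.frame with columns `index`,
#'   `p_active`, `p_inactive` (`p_active > p_inactive`): bits enriched in
#'   inhibitors. Default: 5 bits at 0.7 vs 0.4 on indices drawn from the
#'   seed.
#' @param planted_negative Same, with `p_active < p_inactive`: bits
#'   enriched in non-inhibitors. Default: 5 bits at 0.4 vs 0.7.
#' @param background_p Bit probability for unplanted descriptors
#'   (default 0.3, both classes).
#' @param n_redundant_copies Near-duplicate copies appended per planted
#'   bit (default 0).
#' @param copy_flip_prob Per-bit flip probability of each copy, in
#'   \[0, 0.5) (default 0.05).
#' @param cutoff_nm IC50 cutoff the synthetic activities are generated
#'   around (default 10).
#' @param conflict_fraction Fraction of *extra* compounds appended with
#'   measurements on both sides of the cutoff, to exercise conflict
#'   removal (default 0).
#' @param seed Integer seed; generation is bit-reproducible given the
#'   spec.
#' @return A validated `synthetic_spec`.
#' @export
synthetic_spec <- function(n_active = 508, n_inactive = 2997,
                           n_descriptors = 881,
                           planted_positive = NULL, planted_negative = NULL,
                           background_p = 0.3,
                           n_redundant_copies = 0, copy_flip_prob = 0.05,
                           cutoff_nm = 10, conflict_fraction = 0,
                           seed = 1L) {
  n_active <- assert_count(n_active, "n_active", lower = 1L)
  n_inactive <- assert_count(n_inactive, "n_inactive", lower = 1L)
  n_descriptors <- assert_count(n_descriptors, "n_descriptors", lower = 1L)
  assert_scalar_number(background_p, "background_p", 0, 1, TRUE, TRUE)
  n_redundant_copies <- assert_count(n_redundant_copies, "n_redundant_copies")
  assert_scalar_number(copy_flip_prob, "copy_flip_prob", 0, 0.5,
                       strict_upper = TRUE)
  assert_scalar_number(cutoff_nm, "cutoff_nm", 0, strict_lower = TRUE)
  assert_scalar_number(conflict_fraction, "conflict_fraction", 0, 1,
                       strict_upper = TRUE)

  if (is.null(planted_positive) || is.null(planted_negative)) {
    idx <- with_seed(child_seed(seed, 99L),
                     sample(n_descriptors, 10L))
    if (is.null(planted_positive)) {
      planted_positive <- tibble::tibble(index = idx[1:5],
                                         p_active = 0.7, p_inactive = 0.4)
    }
    if (is.null(planted_negative)) {
      planted_negative <- tibble::tibble(index = idx[6:10],
                                         p_active = 0.4, p_inactive = 0.7)
    }
  }
  planted_positive <- validate_planted(planted_positive, "planted_positive",
                                       n_descriptors, positive = TRUE)
  planted_negative <- validate_planted(planted_negative, "planted_negative",
                                       n_descriptors, positive = FALSE)
  both <- intersect(planted_positive$index, planted_negative$index)
  if (length(both) > 0) abort("planted indices must be unique across lists")

  structure(
    list(n_active = n_active, n_inactive = n_inactive,
         n_descriptors = n_descriptors,
         planted_positive = planted_positive,
         planted_negative = planted_negative,
         background_p = background_p,
         n_redundant_copies = n_redundant_copies,
         copy_flip_prob = copy_flip_prob,
         cutoff_nm = cutoff_nm, conflict_fraction = conflict_fraction,
         seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

validate_planted <- function(tab, name, n_descriptors, positive) {
  tab <- tibble::as_tibble(tab)
  stopifnot(all(c("index", "p_active", "p_inactive") %in% names(tab)))
  if (anyDuplicated(tab$index)) abort(sprintf("%s indices must be unique", name))
  if (any(tab$index < 1 | tab$index > n_descriptors)) {
    abort(sprintf("%s indices out of range", name))
  }
  probs <- c(tab$p_active, tab$p_inactive)
  if (any(probs <= 0 | probs >= 1)) {
    abort(sprintf("%s probabilities must lie in (0, 1)", name))
  }
  cmp <- if (positive) tab$p_active > tab$p_inactive else tab$p_active < tab$p_inactive
  if (!all(cmp)) {
    abort(sprintf("%s requires p_active %s p_inactive", name,
                  if (positive) ">" else "<"))
  }
  tab
}

#' Generate a synthetic activity + fingerprint benchmark
#'
#' Draws the class-conditional Bernoulli fingerprint matrix and a matching
#' activity table described by a [synthetic_spec()]. IC50 values are
#' log-uniform within two decades below the cutoff for inhibitors and two
#' decades above (inclusive) for non-inhibitors, so thresholding the
#' activity table at `cutoff_nm` reconstructs the generated labels exactly.
#' Conflicted extra compounds (when `conflict_fraction > 0`) receive one
#' measurement on each side of the cutoff. SMILES are simple alkane chains
#' — structural placeholders, since the fingerprints here are synthetic
#' bits, not computed from structure.
#'
#' @param spec A [synthetic_spec()].
#' @return List with `activity` (measurement records), `dataset` (the
#'   labeled activity dataset after conflict removal), `fingerprints`
#'   (PaDEL-style tibble, `FP1` ... columns) and `ground_truth` (planted
#'   indices/names, expected scores `100 * (p_active − p_inactive)`, copy
#'   map, seed).
#' @export
#' @examples
#' sim <- generate_synthetic(synthetic_spec(n_active = 20, n_inactive = 30,
#'                                          n_descriptors = 50, seed = 1))
#' dataset_summary(sim$dataset)
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_active + spec$n_inactive
  labels <- rep(c("inhibitor", "non_inhibitor"),
                c(spec$n_active, spec$n_inactive))
  ids <- sprintf("syn%05d", seq_len(n))

  p_active <- rep(spec$background_p, spec$n_descriptors)
  p_inactive <- rep(spec$background_p, spec$n_descriptors)
  p_active[spec$planted_positive$index] <- spec$planted_positive$p_active
  p_inactive[spec$planted_positive$index] <- spec$planted_positive$p_inactive
  p_active[spec$planted_negative$index] <- spec$planted_negative$p_active
  p_inactive[spec$planted_negative$index] <- spec$planted_negative$p_inactive

  out <- with_seed(spec$seed, {
    m <- matrix(0L, nrow = n, ncol = spec$n_descriptors)
    active <- labels == "inhibitor"
    for (j in seq_len(spec$n_descriptors)) {
      m[active, j] <- rbinom(spec$n_active, 1L, p_active[j])
      m[!active, j] <- rbinom(spec$n_inactive, 1L, p_inactive[j])
    }
    colnames(m) <- paste0("FP", seq_len(spec$n_descriptors))

    copy_map <- NULL
    if (spec$n_redundant_copies > 0) {
      parents <- c(spec$planted_positive$index, spec$planted_negative$index)
      copies <- list()
      for (r in seq_len(spec$n_redundant_copies)) {
        for (p in parents) {
          flips <- rbinom(n, 1L, spec$copy_flip_prob)
          copies[[length(copies) + 1L]] <- list(
            parent = paste0("FP", p),
            name = sprintf("FP%d_copy%d", p, r),
            bits = as.integer(xor(m[, p], flips))
          )
        }
      }
      copy_bits <- vapply(copies, `[[`, integer(n), "bits")
      colnames(copy_bits) <- vapply(copies, `[[`, character(1), "name")
      m <- cbind(m, copy_bits)
      copy_map <- tibble::tibble(
        copy = vapply(copies, `[[`, character(1), "name"),
        parent = vapply(copies, `[[`, character(1), "parent")
      )
    }

    ic50 <- ifelse(
      active,
      10^runif(n, log10(spec$cutoff_nm / 100), log10(spec$cutoff_nm)),
      10^runif(n, log10(spec$cutoff_nm), log10(spec$cutoff_nm * 100))
    )
    # strict sides: actives < cutoff, inactives >= cutoff
    ic50[active] <- pmin(ic50[active], spec$cutoff_nm * (1 - 1e-9))
    smiles <- vapply(
      5L + (seq_len(n) %% 6L),
      function(len) paste(rep("C", len), collapse = ""), character(1)
    )
    activity <- tibble::tibble(compound_id = ids, smiles = smiles,
                               ic50_nm = ic50)

    n_conf <- floor(spec$conflict_fraction * n)
    if (n_conf > 0) {
      cids <- sprintf("conf%04d", seq_len(n_conf))
      lo <- 10^runif(n_conf, log10(spec$cutoff_nm / 100), log10(spec$cutoff_nm))
      hi <- 10^runif(n_conf, log10(spec$cutoff_nm), log10(spec$cutoff_nm * 100))
      lo <- pmin(lo, spec$cutoff_nm * (1 - 1e-9))
      conf <- tibble::tibble(
        compound_id = rep(cids, 2L),
        smiles = "CCCCC",
        ic50_nm = c(lo, pmax(hi, spec$cutoff_nm))
      )
      activity <- dplyr::bind_rows(activity, conf)
    }
    list(m = m, activity = activity, copy_map = copy_map)
  })

  fingerprints <- dplyr::bind_cols(tibble::tibble(compound_id = ids),
                                   tibble::as_tibble(out$m))
  dataset <- build_activity_dataset(out$activity, spec$cutoff_nm)
  # generated labels must survive the threshold round-trip
  stopifnot(identical(
    dataset$label[match(ids, dataset$compound_id)], labels
  ))

  ground_truth <- list(
    planted_positive = dplyr::mutate(
      spec$planted_positive,
      descriptor = paste0("FP", .data$index),
      expected_score = 100 * (.data$p_active - .data$p_inactive)
    ),
    planted_negative = dplyr::mutate(
      spec$planted_negative,
      descriptor = paste0("FP", .data$index),
      expected_score = 100 * (.data$p_active - .data$p_inactive)
    ),
    copy_map = out$copy_map,
    background_p = spec$background_p,
    seed = spec$seed
  )

  list(activity = out$activity, dataset = dataset,
       fingerprints = fingerprints, ground_truth = ground_truth,
       spec = spec)
}

#' Tag a synthetic benchmark with a scaffold-like class
#'
#' Marks a random fraction of compounds as members of a named class and
#' forces a chosen *marker* descriptor to 1 for exactly the members, so
#' class membership is recoverable from the matrix. The planted
#' discriminative bits are untouched: the class shares the global
#' structure-activity signal, which is what leave-class-out
#' generalization experiments assume.
#'
#' @param sim Output of [generate_synthetic()].
#' @param class_fraction Fraction of compounds tagged, in (0, 1).
#' @param class_marker_index Descriptor index used as the membership
#'   marker.
#' @param class_name Tag value (default `"classA"`).
#' @param seed Integer seed for the membership draw.
#' @return `sim` with a `scaffold_class` column on `$dataset`, the marker
#'   column rewritten, and `$ground_truth$class` describing the tag.
#' @export
add_class_structure <- function(sim, class_fraction, class_marker_index,
                                class_name = "classA", seed = 1L) {
  assert_scalar_number(class_fraction, "class_fraction", 0, 1, TRUE, TRUE)
  marker <- paste0("FP", assert_count(class_marker_index, "class_marker_index",
                                      lower = 1L))
  if (!marker %in% names(sim$fingerprints)) {
    abort(sprintf("marker descriptor %s not in the matrix", marker))
  }
  n <- nrow(sim$fingerprints)
  member <- with_seed(seed, runif(n) < class_fraction)
  sim$fingerprints[[marker]] <- as.integer(member)
  tags <- ifelse(member, class_name, "other")
  sim$dataset$scaffold_class <-
    tags[match(sim$dataset$compound_id, sim$fingerprints$compound_id)]
  sim$ground_truth$class <- list(
    class_name = class_name, marker = marker,
    n_members = sum(member), fraction = class_fraction, seed = seed
  )
  sim
}
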