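#' Read a molecule activity table
#'
#' Reads one activity measurement per row: a compound identifier, a SMILES
#' string and an IC50 in nanomolar. A compound may appear on several rows
#' (repeated measurements from different assays). Rows whose SMILES does not
#' parse, or whose IC50 is missing or non-positive, are dropped and counted.
#'
#' @param path Path to the input file.
#' @param dialect `"csv"`, `"tsv"` or `"smi"` (SMILES + id, whitespace
#'   separated; activities supplied separately), or `"auto"` to guess from
#'   the file extension.
#' @param activities For `dialect = "smi"`: path to a CSV with columns
#'   `compound_id` and `ic50_nm` to join onto the structures.
#' @param validate_smiles Parse every SMILES and drop invalid rows
#'   (default `TRUE`). Requires ChemmineOB.
#'
#' @return A tibble with columns `compound_id`, `smiles`, `ic50_nm`, one row
#'   per measurement, with attribute `n_rejected` giving the number of
#'   dropped rows.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("compound_id,smiles,ic50_nm", "m1,CCO,5", "m2,c1ccccc1,250"), tf)
#' read_activity_table(tf, validate_smiles = FALSE)
read_activity_table <- function(path, dialect = c("auto", "csv", "tsv", "smi"),
                                activities = NULL, validate_smiles = TRUE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("activity file not found: %s", path))
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- switch(ext, tsv = "tsv", txt = "tsv", smi = "smi", "csv")
  }

  if (dialect == "smi") {
    raw <- readr::read_table(path, col_names = c("smiles", "compound_id"),
                             col_types = "cc", progress = FALSE)
    if (is.null(activities)) {
      abort("dialect 'smi' needs an `activities` CSV with compound_id and ic50_nm")
    }
    act <- readr::read_csv(activities, show_col_types = FALSE, progress = FALSE)
    act <- resolve_activity_columns(act, need_smiles = FALSE)
    tab <- dplyr::inner_join(raw, act, by = "compound_id")
  } else {
    delim <- if (dialect == "tsv") "\t" else ","
    tab <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                             progress = FALSE)
    tab <- resolve_activity_columns(tab, need_smiles = TRUE)
  }

  n_in <- nrow(tab)
  tab <- dplyr::mutate(
    tab,
    compound_id = as.character(.data$compound_id),
    smiles = as.character(.data$smiles),
    ic50_nm = suppressWarnings(as.numeric(.data$ic50_nm))
  )
  ok <- !is.na(tab$compound_id) & !is.na(tab$smiles) &
    !is.na(tab$ic50_nm) & tab$ic50_nm > 0
  if (validate_smiles && any(ok)) {
    ok[ok] <- smiles_is_valid(tab$smiles[ok])
  }
  n_rejected <- sum(!ok)
  if (n_rejected > 0) {
    inform(sprintf("read_activity_table: rejected %d of %d rows (bad SMILES or non-positive IC50)",
                   n_rejected, n_in))
  }
  tab <- tab[ok, c("compound_id", "smiles", "ic50_nm")]
  if (nrow(tab) == 0L) abort("zero valid records in activity table")
  out <- tibble::as_tibble(tab)
  attr(out, "n_rejected") <- n_rejected
  out
}

# Map loosely named columns (or positional columns) onto the canonical
# compound_id / smiles / ic50_nm triple.
resolve_activity_columns <- function(tab, need_smiles = TRUE) {
  nm <- tolower(names(tab))
  pick <- function(cands) {
    hit <- which(nm %in% cands)
    if (length(hit) >= 1) hit[[1]] else NA_integer_
  }
  id_col <- pick(c("compound_id", "id", "name", "cid", "molecule"))
  smi_col <- pick(c("smiles", "smile", "canonical_smiles"))
  ic_col <- pick(c("ic50_nm", "ic50", "ic50(nm)", "activity"))
  wanted <- if (need_smiles) c(id_col, smi_col, ic_col) else c(id_col, ic_col)
  if (anyNA(wanted)) {
    # fall back to positional: id, smiles, ic50
    if (ncol(tab) < (if (need_smiles) 3L else 2L)) {
      abort("cannot resolve compound_id/smiles/ic50_nm columns by header or position")
    }
    if (need_smiles) {
      names(tab)[1:3] <- c("compound_id", "smiles", "ic50_nm")
    } else {
      names(tab)[1:2] <- c("compound_id", "ic50_nm")
    }
  } else {
    names(tab)[id_col] <- "compound_id"
    if (need_smiles) names(tab)[smi_col] <- "smiles"
    names(tab)[ic_col] <- "ic50_nm"
  }
  tab
}

#' Build a labeled activity dataset at an IC50 cutoff
#'
#' Collapses repeated measurements per compound and assigns the binary
#' activity label: a compound is an inhibitor when every one of its IC50
#' measurements is strictly below `cutoff_nm`, a non-inhibitor when every
#' measurement is at or above the cutoff, and is removed as *conflicting*
#' when it has measurements on both sides. Removed compounds are counted in
#' the `n_removed_conflicts` attribute; a measurement exactly at the cutoff
#' counts as non-inhibiting.
#'
#' @param records Tibble of measurements with columns `compound_id`,
#'   `smiles`, `ic50_nm` (from [read_activity_table()] or built in code).
#' @param cutoff_nm Positive IC50 cutoff in nanomolar (10, 100 and 1000 are
#'   the conventional choices).
#'
#' @return A tibble (`compound_id`, `smiles`, `label`) with one row per
#'   surviving compound and attributes `cutoff_nm`, `n_removed_conflicts`
#'   and `split_tag` (`"full"`).
#' @export
#' @examples
#' recs <- tibble::tibble(
#'   compound_id = c("a", "a", "b", "c"),
#'   smiles = c("CCO", "CCO", "CCN", "CCC"),
#'   ic50_nm = c(5, 50, 3, 400)
#' )
#' ds <- build_activity_dataset(recs, cutoff_nm = 10)
#' attr(ds, "n_removed_conflicts")  # compound "a" straddles the cutoff
build_activity_dataset <- function(records, cutoff_nm) {
  assert_scalar_number(cutoff_nm, "cutoff_nm", lower = 0, strict_lower = TRUE)
  stopifnot(all(c("compound_id", "smiles", "ic50_nm") %in% names(records)))
  if (nrow(records) == 0L) abort("no records supplied")

  per <- records %>%
    dplyr::group_by(.data$compound_id) %>%
    dplyr::summarise(
      smiles = dplyr::first(.data$smiles),
      any_active = any(.data$ic50_nm < cutoff_nm),
      any_inactive = any(.data$ic50_nm >= cutoff_nm),
      .groups = "drop"
    )
  conflicted <- per$any_active & per$any_inactive
  n_removed <- sum(conflicted)
  keep <- per[!conflicted, ]
  if (nrow(keep) == 0L) abort("empty dataset after conflict removal")

  out <- tibble::tibble(
    compound_id = keep$compound_id,
    smiles = keep$smiles,
    label = ifelse(keep$any_active, "inhibitor", "non_inhibitor")
  )
  new_activity_dataset(out, cutoff_nm = cutoff_nm,
                       n_removed_conflicts = n_removed, split_tag = "full")
}

new_activity_dataset <- function(tab, cutoff_nm = NA_real_,
                                 n_removed_conflicts = 0L, split_tag = "full") {
  out <- tibble::as_tibble(tab)
  assert_labels(out$label)
  if (anyDuplicated(out$compound_id)) {
    abort("compound_id values must be unique in an activity dataset")
  }
  attr(out, "cutoff_nm") <- cutoff_nm
  attr(out, "n_removed_conflicts") <- as.integer(n_removed_conflicts)
  attr(out, "split_tag") <- split_tag
  class(out) <- c("activity_dataset", class(out))
  out
}

#' @export
print.activity_dataset <- function(x, ...) {
  n_act <- sum(x$label == "inhibitor")
  cat(sprintf("<activity_dataset> %d compounds (%d inhibitors, %d non-inhibitors)\n",
              nrow(x), n_act, nrow(x) - n_act))
  cat(sprintf("  cutoff: %s nM | split: %s | conflicts removed: %d\n",
              format(attr(x, "cutoff_nm")), attr(x, "split_tag"),
              attr(x, "n_removed_conflicts")))
  NextMethod()
}

#' Summarise an activity dataset
#'
#' @param ds An activity dataset tibble.
#' @return One-row tibble with the cutoff, class counts and the number of
#'   compounds removed for conflicting measurements.
#' @export
dataset_summary <- function(ds) {
  tibble::tibble(
    cutoff_nm = attr(ds, "cutoff_nm") %||% NA_real_,
    split_tag = attr(ds, "split_tag") %||% "full",
    n_compounds = nrow(ds),
    n_active = sum(ds$label == "inhibitor"),
    n_inactive = sum(ds$label == "non_inhibitor"),
    n_removed_conflicts = attr(ds, "n_removed_conflicts") %||% NA_integer_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stratified train/validation split
#'
#' Randomly assigns a fixed fraction of each label class to the validation
#' set, so the rare inhibitor class stays represented in both parts. Per
#' class, `round(fraction * class size)` compounds (at least 1, at most
#' size − 1) go to validation. Deterministic given `seed`.
#'
#' @param ds Activity dataset (needs `compound_id` and `label` columns).
#' @param validation_fraction Fraction held out, in (0, 1). Default 0.1 —
#'   the conventional 90/10 split.
#' @param seed Integer seed controlling the assignment.
#'
#' @return A list with elements `train` and `validation`, both activity
#'   datasets inheriting the parent's cutoff, tagged via their `split_tag`
#'   attribute.
#' @export
split_train_validation <- function(ds, validation_fraction = 0.1, seed) {
  assert_scalar_number(validation_fraction, "validation_fraction",
                       lower = 0, upper = 1, strict_lower = TRUE,
                       strict_upper = TRUE)
  counts <- table(ds$label)
  if (length(counts) < 2L || any(counts < 2L)) {
    abort("each label class needs at least 2 compounds to stratify the split")
  }
  idx_val <- with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(ds)), ds$label), function(idx) {
      k <- round(validation_fraction * length(idx))
      k <- max(1L, min(length(idx) - 1L, k))
      sample(idx, k)
    }), use.names = FALSE)
  })
  mk <- function(rows, tag) {
    new_activity_dataset(
      ds[rows, c("compound_id", "smiles", "label")],
      cutoff_nm = attr(ds, "cutoff_nm") %||% NA_real_,
      n_removed_conflicts = attr(ds, "n_removed_conflicts") %||% 0L,
      split_tag = tag
    )
  }
  list(
    train = mk(setdiff(seq_len(nrow(ds)), idx_val), "train"),
    validation = mk(sort(idx_val), "validation")
  )
}
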