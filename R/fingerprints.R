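#' Read a binary fingerprint matrix
#'
#' Reads the PaDEL output dialect: a CSV whose first column (`Name`) holds
#' the compound id and whose remaining columns are named binary descriptors
#' (for the PubChem scheme, `PubchemFP0` ... or `FP1` ... `FP881`). A dense
#' headerless matrix is also accepted when a `names_file` sidecar supplies
#' the descriptor names, one per line.
#'
#' @param path CSV path.
#' @param names_file Optional sidecar with descriptor names for headerless
#'   input.
#' @return Tibble with `compound_id` followed by integer 0/1 descriptor
#'   columns.
#' @export
read_fingerprint_matrix <- function(path, names_file = NULL) {
  if (!file.exists(path)) abort(sprintf("fingerprint file not found: %s", path))
  if (is.null(names_file)) {
    tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
    names(tab)[1] <- "compound_id"
  } else {
    tab <- readr::read_csv(path, col_names = FALSE, show_col_types = FALSE,
                           progress = FALSE)
    nms <- readLines(names_file)
    if (length(nms) != ncol(tab) - 1L) {
      abort("names_file length does not match the matrix column count")
    }
    names(tab) <- c("compound_id", nms)
  }
  tab$compound_id <- as.character(tab$compound_id)
  validate_fingerprints(tab)
}

#' Write a fingerprint matrix in the PaDEL CSV dialect
#'
#' @param fp Fingerprint tibble.
#' @param path Output path.
#' @export
write_fingerprint_matrix <- function(fp, path) {
  out <- fp
  names(out)[1] <- "Name"
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

validate_fingerprints <- function(fp) {
  if (!"compound_id" %in% names(fp)) {
    abort("fingerprint table needs a compound_id column")
  }
  if (anyDuplicated(fp$compound_id)) abort("duplicate compound_id in fingerprints")
  if (anyDuplicated(names(fp))) abort("duplicate descriptor names")
  bits <- fp[setdiff(names(fp), "compound_id")]
  bad <- !vapply(bits, function(col) all(col %in% c(0L, 1L)), logical(1))
  if (any(bad)) {
    abort(sprintf("non-binary descriptor columns: %s",
                  paste(names(bits)[bad][seq_len(min(5, sum(bad)))],
                        collapse = ", ")))
  }
  fp[setdiff(names(fp), "compound_id")] <-
    lapply(bits, function(col) as.integer(col))
  tibble::as_tibble(fp)
}

# Dense integer matrix view, compounds in rows.
fp_as_matrix <- function(fp) {
  m <- as.matrix(fp[setdiff(names(fp), "compound_id")])
  storage.mode(m) <- "integer"
  rownames(m) <- fp$compound_id
  m
}

#' Align a fingerprint matrix to an activity dataset
#'
#' Reorders (and subsets) fingerprint rows to match the dataset's compound
#' order, erroring on compounds without fingerprints.
#'
#' @param fp Fingerprint tibble.
#' @param ds Activity dataset (or any tibble with `compound_id`).
#' @return Fingerprint tibble with rows in `ds` order.
#' @export
align_fingerprints <- function(fp, ds) {
  pos <- match(ds$compound_id, fp$compound_id)
  if (anyNA(pos)) {
    missing <- ds$compound_id[is.na(pos)]
    abort(sprintf("no fingerprints for %d compound(s), e.g. %s",
                  length(missing),
                  paste(sQuote(head(missing, 3)), collapse = ", ")))
  }
  fp[pos, , drop = FALSE]
}
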