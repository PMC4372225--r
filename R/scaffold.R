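#' Parse SMILES strings to an SDF set
#'
#' Thin wrapper over ChemmineR/OpenBabel that parses a character vector of
#' SMILES, preserving order and names. Errors on any unparseable SMILES.
#'
#' @param smiles Character vector of SMILES.
#' @param ids Optional compound ids used as molecule names.
#' @return A `ChemmineR::SDFset`.
#' @export
parse_smiles <- function(smiles, ids = NULL) {
  if (length(smiles) == 0L) abort("no SMILES supplied")
  if (is.null(ids)) ids <- paste0("mol", seq_along(smiles))
  ok <- smiles_is_valid(smiles)
  if (!all(ok)) {
    abort(sprintf("invalid SMILES: %s",
                  paste(sQuote(smiles[!ok][seq_len(min(5, sum(!ok)))]),
                        collapse = ", ")))
  }
  sdf <- ChemmineR::smiles2sdf(setNames(smiles, ids))
  ChemmineR::cid(sdf) <- ids
  sdf
}

#' Check whether SMILES strings parse
#'
#' @param smiles Character vector.
#' @return Logical vector, `TRUE` where the SMILES yields a molecule with at
#'   least one atom.
#' @export
smiles_is_valid <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(FALSE)
    sdf <- tryCatch(
      suppressWarnings(ChemmineR::smiles2sdf(s)),
      error = function(e) NULL
    )
    if (is.null(sdf) || length(sdf) == 0L) return(FALSE)
    nrow(ChemmineR::atomblock(sdf[[1]])) > 0
  }, logical(1), USE.NAMES = FALSE)
}

#' Default scaffold-class registry
#'
#' Substructure patterns for the dominant structural classes, with a
#' priority rank used to resolve overlaps: every quinazoline contains a
#' pyrimidine ring, so the fused benzo-pyrimidine pattern is tried first.
#'
#' @return Tibble with columns `class_name`, `smarts`, `priority` (lower
#'   number = tried first).
#' @export
scaffold_registry <- function() {
  tibble::tibble(
    class_name = c("quinazoline", "pyrimidine"),
    smarts = c("c1ccc2ncncc2c1", "c1ccncn1"),
    priority = c(1L, 2L)
  )
}

validate_registry <- function(registry) {
  stopifnot(all(c("class_name", "smarts", "priority") %in% names(registry)))
  if (nrow(registry) == 0L) abort("class registry is empty")
  if (anyDuplicated(registry$priority)) {
    abort("class registry priorities must be unique")
  }
  registry[order(registry$priority), ]
}

#' Assign a scaffold class to each molecule
#'
#' Matches each molecule against the registry's substructure patterns in
#' priority order and returns the first class that matches; molecules
#' matching no pattern get `"other"`.
#'
#' @param smiles Character vector of valid SMILES.
#' @param registry Class registry, see [scaffold_registry()].
#' @return Character vector of class names, same length as `smiles`.
#' @export
#' @examples
#' \dontrun{
#' assign_scaffold_class(c("c1ccncn1", "c1ccccc1"))  # "pyrimidine", "other"
#' }
assign_scaffold_class <- function(smiles, registry = scaffold_registry()) {
  registry <- validate_registry(registry)
  sdf <- parse_smiles(smiles)
  out <- rep("other", length(smiles))
  undecided <- rep(TRUE, length(smiles))
  for (i in seq_len(nrow(registry))) {
    hits <- ChemmineR::smartsSearchOB(sdf, registry$smarts[i],
                                      uniqueMatches = TRUE) > 0
    take <- undecided & hits
    out[take] <- registry$class_name[i]
    undecided <- undecided & !take
    if (!any(undecided)) break
  }
  out
}

#' Annotate an activity dataset with scaffold classes
#'
#' Adds a `scaffold_class` column by substructure matching. Downstream
#' subsetting functions use this column when present, which also lets
#' synthetic datasets carry externally assigned class tags.
#'
#' @inheritParams assign_scaffold_class
#' @param ds Activity dataset.
#' @return `ds` with a `scaffold_class` column.
#' @export
annotate_scaffold_class <- function(ds, registry = scaffold_registry()) {
  ds$scaffold_class <- assign_scaffold_class(ds$smiles, registry)
  ds
}

dataset_classes <- function(ds, registry) {
  if ("scaffold_class" %in% names(ds)) return(ds$scaffold_class)
  assign_scaffold_class(ds$smiles, registry)
}

rebuild_subset <- function(ds, rows, split_tag = NULL) {
  out <- ds[rows, , drop = FALSE]
  new_activity_dataset(
    out[, setdiff(names(out), character(0))],
    cutoff_nm = attr(ds, "cutoff_nm") %||% NA_real_,
    n_removed_conflicts = attr(ds, "n_removed_conflicts") %||% 0L,
    split_tag = split_tag %||% (attr(ds, "split_tag") %||% "full")
  )
}

#' Subset an activity dataset to one scaffold class
#'
#' @param ds Activity dataset (labels are preserved, never recomputed).
#' @param class_name Scaffold class to keep.
#' @param registry Class registry used when `ds` has no `scaffold_class`
#'   column.
#' @return Activity dataset containing only the matching compounds.
#' @export
scaffold_subset <- function(ds, class_name, registry = scaffold_registry()) {
  cls <- dataset_classes(ds, registry)
  rows <- which(cls == class_name)
  if (length(rows) == 0L) {
    abort(sprintf("no compounds in class '%s'", class_name))
  }
  rebuild_subset(ds, rows)
}

#' Leave-one-class-out complement of a dataset
#'
#' Returns every compound *not* in the given scaffold class — the training
#' set of a leave-class-out generalization experiment. By construction no
#' compound in the result matches the class pattern, which is asserted.
#'
#' @inheritParams scaffold_subset
#' @return Activity dataset of all compounds outside `class_name`.
#' @export
leave_class_out <- function(ds, class_name, registry = scaffold_registry()) {
  cls <- dataset_classes(ds, registry)
  rows <- which(cls != class_name)
  if (length(rows) == 0L) {
    abort(sprintf("leaving out class '%s' empties the dataset", class_name))
  }
  out <- rebuild_subset(ds, rows)
  stopifnot(!any(dataset_classes(out, registry) == class_name))
  out
}
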