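#' Default functional-group registry
#'
#' Substructure patterns for the groups most informative about kinase
#' inhibitor chemistry: secondary amines (R2NH, the anilino linkage of
#' 4-anilinoquinazoline inhibitors), tertiary amines (R3N, common in
#' solubilising side chains) and the ring count. Amide nitrogens are
#' excluded from the amine patterns. The `rings` entry has no SMARTS: ring
#' count is the cyclomatic number (bonds − atoms + connected components),
#' which equals the size of the smallest set of smallest rings.
#'
#' @return Tibble with columns `group` and `smarts` (`NA` for `rings`).
#' @export
functional_group_registry <- function() {
  tibble::tibble(
    group = c("secondary_amine", "tertiary_amine", "rings"),
    smarts = c("[NX3;H1;!$(NC=O)]([#6])[#6]",
               "[NX3;H0;!$(NC=O)]([#6])([#6])[#6]",
               NA_character_)
  )
}

#' Count functional groups per molecule
#'
#' @param smiles Character vector of SMILES.
#' @param registry Functional-group registry, see
#'   [functional_group_registry()].
#' @return Tibble with one row per valid molecule (`smiles`, one count
#'   column per group). Invalid SMILES are skipped with a message; the
#'   number skipped is in attribute `n_skipped`.
#' @export
#' @examples
#' \dontrun{
#' count_functional_groups(c("CNC", "CN(C)C", "c1ccc2ccccc2c1"))
#' }
count_functional_groups <- function(smiles, registry = functional_group_registry()) {
  stopifnot(nrow(registry) > 0, "group" %in% names(registry))
  ok <- smiles_is_valid(smiles)
  n_skipped <- sum(!ok)
  if (n_skipped > 0) {
    inform(sprintf("count_functional_groups: skipped %d invalid SMILES", n_skipped))
  }
  smiles <- smiles[ok]
  if (length(smiles) == 0L) abort("no valid SMILES to profile")
  sdf <- parse_smiles(smiles)
  counts <- lapply(seq_len(nrow(registry)), function(i) {
    if (is.na(registry$smarts[i])) {
      vapply(seq_along(sdf), function(k) ring_count_sdf(sdf[[k]]), numeric(1))
    } else {
      as.numeric(ChemmineR::smartsSearchOB(sdf, registry$smarts[i],
                                           uniqueMatches = TRUE))
    }
  })
  out <- tibble::as_tibble(setNames(counts, registry$group))
  out <- dplyr::bind_cols(tibble::tibble(smiles = smiles), out)
  attr(out, "n_skipped") <- n_skipped
  out
}

# SSSR ring count via the cyclomatic number of the heavy-atom graph.
ring_count_sdf <- function(sdf_mol) {
  ab <- ChemmineR::atomblock(sdf_mol)
  bb <- ChemmineR::bondblock(sdf_mol)
  n_atoms <- nrow(ab)
  n_bonds <- if (is.null(bb)) 0L else nrow(bb)
  if (n_atoms == 0L) return(0)
  comp <- n_components(n_atoms, bb)
  n_bonds - n_atoms + comp
}

# Connected components by union-find on the bond list.
n_components <- function(n_atoms, bondblock) {
  parent <- seq_len(n_atoms)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (!is.null(bondblock) && nrow(bondblock) > 0) {
    for (b in seq_len(nrow(bondblock))) {
      ra <- find(as.integer(bondblock[b, 1]))
      rb <- find(as.integer(bondblock[b, 2]))
      if (ra != rb) parent[ra] <- as.integer(rb)
    }
  }
  length(unique(vapply(seq_len(n_atoms), find, numeric(1))))
}

#' Functional-group frequency profile by activity class
#'
#' Computes, for each functional group in the registry, the mean and
#' standard deviation of its per-molecule count within each activity
#' class — the summary used to contrast group usage between inhibitors and
#' non-inhibitors.
#'
#' @param ds Activity dataset (`smiles` + `label` columns).
#' @param registry Functional-group registry.
#' @return Tibble with columns `group`, `label`, `mean`, `sd`, `n`, classed
#'   for [autoplot()].
#' @export
functional_group_profile <- function(ds, registry = functional_group_registry()) {
  stopifnot(all(c("smiles", "label") %in% names(ds)))
  ok <- smiles_is_valid(ds$smiles)
  if (!any(ok)) abort("no valid SMILES to profile")
  if (any(!ok)) {
    inform(sprintf("functional_group_profile: skipped %d invalid SMILES",
                   sum(!ok)))
  }
  counts <- count_functional_groups(ds$smiles[ok], registry)
  counts$label <- as.character(ds$label[ok])
  out <- counts %>%
    tidyr::pivot_longer(dplyr::all_of(registry$group),
                        names_to = "group", values_to = "count") %>%
    dplyr::group_by(.data$group, .data$label) %>%
    dplyr::summarise(
      mean = mean(.data$count),
      sd = sd(.data$count),
      n = dplyr::n(),
      .groups = "drop"
    )
  class(out) <- c("fg_profile", class(out))
  out
}
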