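# Protein-nucleic-acid contact mapping and chain labeling.

#' Map protein residues in contact with nucleic acid
#'
#' A protein residue is a binding residue when any of its heavy (non-hydrogen)
#' atoms lies strictly below `cutoff_angstrom` from any heavy atom of any
#' chain of the requested nucleic-acid kind. Hydrogens are excluded on both
#' sides; the comparison is strict (`<`), so an atom pair at exactly the
#' cutoff does not count.
#'
#' @param model An `na_structure` from [parse_pdb()].
#' @param cutoff_angstrom Contact distance cutoff in Angstrom (default 5.0).
#' @param na_kind `"DNA"` or `"RNA"`: which nucleic-acid chains to use.
#' @return Tibble with columns `chain_id` and `residue_index` (0-based over
#'   the chain's resolved residues), one row per contacting protein residue.
#' @examples
#' toy <- make_toy_structure(n_residues = 15, binding_positions = c(2, 9))
#' model <- parse_pdb(toy$pdb_text)
#' map_contacts(model, na_kind = "DNA")
#' @export
map_contacts <- function(model, cutoff_angstrom = 5.0, na_kind = c("DNA", "RNA")) {
  stopifnot(inherits(model, "na_structure"), cutoff_angstrom > 0)
  na_kind <- match.arg(na_kind)
  prot_chains <- model$chains$chain_id[model$chains$kind == "protein"]
  na_chains <- model$chains$chain_id[model$chains$kind == na_kind]
  if (length(prot_chains) == 0) {
    stop("model contains no protein chain", call. = FALSE)
  }
  if (length(na_chains) == 0) {
    stop(sprintf("model contains no %s chain", na_kind), call. = FALSE)
  }
  pa <- model$atoms[model$atoms$chain_id %in% prot_chains &
                      !model$atoms$is_hydrogen, ]
  qa <- model$atoms[model$atoms$chain_id %in% na_chains &
                      !model$atoms$is_hydrogen, ]
  if (nrow(pa) == 0 || nrow(qa) == 0) {
    return(tibble::tibble(chain_id = character(), residue_index = integer()))
  }
  P <- cbind(pa$x, pa$y, pa$z)
  Q <- cbind(qa$x, qa$y, qa$z)
  # squared cross-distances; strict comparison against cutoff^2
  d2 <- outer(rowSums(P^2), rep(1, nrow(Q))) +
    outer(rep(1, nrow(P)), rowSums(Q^2)) - 2 * tcrossprod(P, Q)
  hit <- apply(d2, 1, min) < cutoff_angstrom^2 - 1e-12
  out <- pa[hit, c("chain_id", "residue_index")]
  dplyr::distinct(dplyr::arrange(out, .data$chain_id, .data$residue_index))
}

#' Label protein chains by their nucleic-acid contacts
#'
#' Builds one labeled chain per protein chain having at least one contact;
#' chains without contacts are dropped. Labels live on the SEQRES-derived
#' sequence: the structure-resolved sequence is globally aligned to it, so
#' residues absent from the coordinates get `resolved = FALSE` and can never
#' be labeled 1.
#'
#' @param model An `na_structure`.
#' @param contacts Contact table from [map_contacts()] on the same model.
#' @param na_kind `"DNA"` or `"RNA"`, recorded on each labeled chain.
#' @return Tibble of class `na_labeled_chains`, one row per retained chain:
#'   `structure_id`, `chain_id`, `na_kind`, `sequence` (SEQRES-derived),
#'   and list-columns `labels` (integer 0/1 per residue) and `resolved`
#'   (logical per residue).
#' @export
label_chains <- function(model, contacts, na_kind = c("DNA", "RNA")) {
  stopifnot(inherits(model, "na_structure"))
  na_kind <- match.arg(na_kind)
  keep <- unique(contacts$chain_id)
  rows <- lapply(keep, function(cid) {
    ch <- model$chains[model$chains$chain_id == cid, ]
    if (ch$kind != "protein") return(NULL)
    full <- ch$seqres_sequence
    struct <- ch$atom_sequence
    if (identical(full, struct)) {
      mapping <- seq_len(nchar(full)) - 1L
    } else {
      mapping <- align_full_to_structure(full, struct)
    }
    ci <- contacts$residue_index[contacts$chain_id == cid]
    labels <- integer(nchar(full))
    labels[!is.na(mapping) & mapping %in% ci] <- 1L
    tibble::tibble(structure_id = model$structure_id, chain_id = cid,
                   na_kind = na_kind, sequence = full,
                   labels = list(labels), resolved = list(!is.na(mapping)))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble::tibble(structure_id = character(), chain_id = character(),
                          na_kind = character(), sequence = character(),
                          labels = list(), resolved = list())
  }
  class(out) <- c("na_labeled_chains", class(out))
  out
}

#' Filter labeled chains by length and undetermined residues
#'
#' Drops chains shorter than `min_len` residues and chains whose sequence
#' contains an undetermined residue `'X'`. Idempotent.
#'
#' @param chains A labeled-chains tibble (or any tibble with a `sequence`
#'   column).
#' @param min_len Minimum sequence length retained (default 30).
#' @return The filtered tibble.
#' @export
filter_sequences <- function(chains, min_len = 30) {
  dplyr::filter(chains, nchar(.data$sequence) >= min_len,
                !grepl("X", .data$sequence, fixed = TRUE))
}

#' Mark unresolved residues on a labeled chain
#'
#' Given the full-to-structure position mapping for one chain, sets
#' `resolved` to `FALSE` exactly where the mapping is `NA` and clears any
#' label there. Unresolved residues are excluded as training examples but
#' keep their sequence identity, so they still contribute to neighbours'
#' sliding windows.
#'
#' @param labeled One row of an `na_labeled_chains` tibble.
#' @param mapping Integer vector from [align_full_to_structure()], one entry
#'   per residue of `labeled$sequence`.
#' @return The updated one-row tibble.
#' @export
mask_unresolved <- function(labeled, mapping) {
  stopifnot(nrow(labeled) == 1)
  n <- nchar(labeled$sequence)
  if (length(mapping) != n) {
    stop(sprintf("mapping length %d does not match sequence length %d",
                 length(mapping), n), call. = FALSE)
  }
  resolved <- !is.na(mapping)
  labels <- labeled$labels[[1]]
  labels[!resolved] <- 0L
  labeled$labels <- list(labels)
  labeled$resolved <- list(resolved)
  labeled
}
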