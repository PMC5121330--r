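# Parsing of co-complex structures and chain classification.
#
# `parse_pdb()` wraps bio3d::read.pdb behind a contract the rest of the
# package relies on: atoms and residues in a tidy table, residues indexed
# 0-based in file order within each chain, the first alternate location kept,
# hydrogens flagged, HETATM residues attached to their chain, and the SEQRES
# sequence captured when present.

#' Parse a PDB-format co-complex structure
#'
#' Reads ATOM/HETATM/SEQRES/TER records from PDB-format text. Coordinates are
#' validated up front so a malformed field is reported with its line number.
#' Only the first alternate location of each atom is retained; residues are
#' ordered by file appearance and indexed 0-based within their chain.
#' Hydrogens are detected from the element column when present, otherwise
#' from the atom name with leading digits stripped.
#'
#' @param text A single string of PDB-format text, or a path to a PDB file.
#' @param structure_id Identifier recorded on the result (default `"struct"`).
#' @return An object of class `na_structure`: a list with
#'   * `structure_id`,
#'   * `atoms`: tibble with one row per atom (`chain_id`, `residue_index`
#'     0-based over resolved residues, `resname`, `one_letter`, `atom`,
#'     `element`, `is_hydrogen`, `x`, `y`, `z`),
#'   * `chains`: tibble with one row per chain (`chain_id`, `kind`,
#'     `n_resolved`, `atom_sequence`, `seqres_sequence`). For chains without
#'     SEQRES records the sequence is reconstructed from the ATOM records.
#' @examples
#' toy <- make_toy_structure(n_residues = 12, binding_positions = c(3, 7))
#' model <- parse_pdb(toy$pdb_text)
#' model$chains
#' @export
parse_pdb <- function(text, structure_id = "struct") {
  stopifnot(is.character(text), length(text) == 1)
  if (!grepl("\n", text) && file.exists(text)) {
    text <- paste(readLines(text, warn = FALSE), collapse = "\n")
  }
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(grepl("^ATOM  ", lines))) {
    stop("no ATOM records found in PDB text", call. = FALSE)
  }
  for (i in which(is_atom)) {
    ln <- lines[i]
    if (nchar(ln) < 54) {
      stop(sprintf("malformed ATOM/HETATM record at line %d: too short", i),
           call. = FALSE)
    }
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (anyNA(xyz) || any(!is.finite(xyz))) {
      stop(sprintf("malformed coordinate fields at line %d", i),
           call. = FALSE)
    }
  }

  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(lines, tf)
  pdb <- bio3d::read.pdb(tf, rm.alt = TRUE, verbose = FALSE)

  at <- tibble::as_tibble(pdb$atom)
  at$chain[is.na(at$chain)] <- " "
  at$insert[is.na(at$insert)] <- ""
  elem <- toupper(trimws(ifelse(is.na(at$elesy), "", at$elesy)))
  name_guess <- toupper(sub("^[0-9]+", "", trimws(at$elety)))
  elem[elem == ""] <- substr(name_guess[elem == ""], 1, 1)
  is_h <- elem == "H" | elem == "D"

  atoms <- tibble::tibble(
    chain_id = at$chain,
    resname  = toupper(trimws(at$resid)),
    resno    = at$resno,
    insert   = at$insert,
    atom     = trimws(at$elety),
    element  = elem,
    is_hydrogen = is_h,
    x = at$x, y = at$y, z = at$z
  )
  # residues ordered by file appearance within chain, 0-based
  key <- paste(atoms$chain_id, atoms$resno, atoms$insert, atoms$resname,
               sep = "\r")
  atoms <- atoms |>
    dplyr::group_by(.data$chain_id) |>
    dplyr::mutate(residue_index = match(key[dplyr::cur_group_rows()],
                                        unique(key[dplyr::cur_group_rows()])) - 1L) |>
    dplyr::ungroup() |>
    dplyr::mutate(one_letter = residue_one_letter(.data$resname)) |>
    dplyr::select("chain_id", "residue_index", "resname", "one_letter",
                  "atom", "element", "is_hydrogen", "x", "y", "z")

  res_tbl <- atoms |>
    dplyr::distinct(.data$chain_id, .data$residue_index, .data$resname,
                    .data$one_letter)
  seqres <- pdb$seqres
  chains <- res_tbl |>
    dplyr::group_by(.data$chain_id) |>
    dplyr::summarise(
      kind = classify_chain(.data$resname),
      n_resolved = dplyr::n(),
      atom_sequence = paste(.data$one_letter, collapse = ""),
      .groups = "drop"
    )
  chains$seqres_sequence <- vapply(seq_len(nrow(chains)), function(i) {
    cid <- chains$chain_id[i]
    sr <- seqres[names(seqres) == cid]
    if (length(sr) == 0) chains$atom_sequence[i]
    else paste(residue_one_letter(sr), collapse = "")
  }, character(1))

  structure(list(structure_id = structure_id, atoms = atoms, chains = chains),
            class = "na_structure")
}

#' @export
print.na_structure <- function(x, ...) {
  cat("<na_structure> ", x$structure_id, ": ", nrow(x$chains), " chain(s), ",
      nrow(x$atoms), " atoms\n", sep = "")
  print(x$chains)
  invisible(x)
}

#' Classify a chain as protein, DNA, RNA or other
#'
#' Majority rule over residue names: DNA if most residues are in
#' {DA, DC, DG, DT, DI}, RNA if in {A, C, G, U, I}, protein if most are
#' standard (or mapped modified) amino acids, otherwise `"other"`.
#'
#' @param resnames Character vector of residue names for one chain.
#' @return One of `"protein"`, `"DNA"`, `"RNA"`, `"other"`.
#' @export
classify_chain <- function(resnames) {
  resnames <- toupper(trimws(resnames))
  if (length(resnames) == 0) stop("empty chain", call. = FALSE)
  n <- length(resnames)
  votes <- c(
    DNA = sum(resnames %in% DNA_CODES),
    RNA = sum(resnames %in% RNA_CODES),
    protein = sum(resnames %in% c(names(AA3), names(AA3_MODIFIED)))
  )
  if (max(votes) * 2 <= n) return("other")
  names(votes)[which.max(votes)]
}
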