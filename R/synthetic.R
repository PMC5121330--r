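# Seeded synthetic-data generators: toy co-complex structures with known
# contacts, synthetic alignments with controlled column conservation, and
# planted-signal datasets exercising the full two-stage pipeline.
#
# The geometry is deliberately minimal (a stretched backbone trace and a
# phosphate-proxy nucleotide ladder): the contact rule is atom-agnostic, so
# a single heavy atom per nucleotide at a known distance is enough to test
# it exactly.

pdb_atom_line <- function(serial, name, resname, chain, resno, x, y, z,
                          element, het = FALSE) {
  sprintf("%-6s%5d  %-3s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          if (het) "HETATM" else "ATOM", serial, name, resname, chain, resno,
          x, y, z, 1, 0, element)
}

pdb_seqres_lines <- function(chain, resnames) {
  n <- length(resnames)
  rows <- split(resnames, ceiling(seq_along(resnames) / 13))
  vapply(seq_along(rows), function(i) {
    sprintf("SEQRES %3d %1s %4d  %s", i, chain, n,
            paste(sprintf("%3s", rows[[i]]), collapse = " "))
  }, character(1))
}

#' Generate a toy protein-nucleic-acid co-complex structure
#'
#' Lays a protein chain (chain A; N, CA, CB per residue) along a stretched
#' trace and places one phosphate-proxy nucleotide (chain B) exactly
#' `contact_distance` from the CB of every requested binding position, so
#' every binding residue has a heavy atom strictly inside the 5-Angstrom
#' rule and every other residue's nearest nucleic-acid heavy atom lies
#' beyond `non_contact_distance`. The emitted text round-trips through
#' [parse_pdb()] and the ground truth always equals a brute-force distance
#' scan.
#'
#' @param n_residues Protein chain length.
#' @param binding_positions 0-based indices of binding residues (may be
#'   empty; a far-away nucleotide is still emitted so the structure has a
#'   nucleic-acid chain).
#' @param contact_distance Planted contact distance, must be `< 5` (default
#'   4.5).
#' @param non_contact_distance Minimum distance of every non-binding residue
#'   to the nucleic acid, must be `> 5` (default 8).
#' @param na_kind `"DNA"` or `"RNA"` nucleotide codes for chain B.
#' @param seed Seed for the sequence and the coordinate jitter.
#' @param unresolved_positions 0-based positions present in SEQRES but
#'   omitted from the ATOM records (must not be binding positions).
#' @param decoy_hydrogens If `TRUE`, adds nucleic-acid hydrogen atoms within
#'   3 Angstrom of non-binding residues; they must be ignored by the contact
#'   rule.
#' @param structure_id Id written on the parsed structure.
#' @return List: `pdb_text`, `contacts` (ground-truth tibble of resolved
#'   residue indices in contact), `labels` (0/1 per SEQRES position),
#'   `sequence`, `na_kind`, `structure_id`.
#' @export
make_toy_structure <- function(n_residues, binding_positions = integer(),
                               contact_distance = 4.5,
                               non_contact_distance = 8,
                               na_kind = c("DNA", "RNA"), seed = 1,
                               unresolved_positions = integer(),
                               decoy_hydrogens = FALSE,
                               structure_id = "TOY") {
  na_kind <- match.arg(na_kind)
  binding_positions <- sort(unique(as.integer(binding_positions)))
  unresolved_positions <- sort(unique(as.integer(unresolved_positions)))
  stopifnot(n_residues >= 1)
  if (length(binding_positions) &&
      (min(binding_positions) < 0 || max(binding_positions) >= n_residues)) {
    stop("binding_positions out of range", call. = FALSE)
  }
  if (!(contact_distance < 5 && 5 < non_contact_distance)) {
    stop("need contact_distance < 5 < non_contact_distance", call. = FALSE)
  }
  if (length(intersect(binding_positions, unresolved_positions))) {
    stop("unresolved positions cannot be binding positions", call. = FALSE)
  }
  spacing <- 10
  # feasibility: a nucleotide 'contact_distance' above residue i must clear
  # 'non_contact_distance' from residue i +/- 1 (jitter margin 1 Angstrom)
  if (sqrt(spacing^2 + contact_distance^2) - 1 <= non_contact_distance) {
    stop("geometrically infeasible spec: contact and exclusion constraints overlap",
         call. = FALSE)
  }
  withr::with_seed(seed, {
    seqv <- sample(AA1, n_residues, replace = TRUE)
    jit <- matrix(stats::runif(n_residues * 2, -0.3, 0.3), ncol = 2)
  })
  resnames <- names(AA3)[match(seqv, AA3)]
  ca <- cbind(spacing * (seq_len(n_residues) - 1) + jit[, 1], jit[, 2], 0)

  lines <- pdb_seqres_lines("A", resnames)
  serial <- 0L
  resolved <- setdiff(seq_len(n_residues) - 1L, unresolved_positions)
  for (i0 in resolved) {
    i <- i0 + 1L
    for (a in list(c("N", -0.7, 1.0, 0), c("CA", 0, 0, 0), c("CB", 0, 0, 1))) {
      serial <- serial + 1L
      lines <- c(lines, pdb_atom_line(
        serial, a[1], resnames[i], "A", i,
        ca[i, 1] + as.numeric(a[2]), ca[i, 2] + as.numeric(a[3]),
        ca[i, 3] + as.numeric(a[4]),
        substr(a[1], 1, 1)))
    }
  }
  lines <- c(lines, "TER")

  nt_codes <- if (na_kind == "DNA") c("DA", "DC", "DG", "DT") else c("A", "C", "G", "U")
  nt_at <- function(resno, x, y, z, name = "P", element = "P") {
    pdb_atom_line(serial <<- serial + 1L, name,
                  nt_codes[(resno - 1) %% 4 + 1], "B", resno, x, y, z,
                  element, het = FALSE)
  }
  resno_b <- 0L
  if (length(binding_positions)) {
    for (b in binding_positions) {
      resno_b <- resno_b + 1L
      # CB sits at ca + (0,0,1); nucleotide exactly contact_distance above it
      lines <- c(lines, nt_at(resno_b, ca[b + 1, 1], ca[b + 1, 2],
                              1 + contact_distance))
    }
  } else {
    resno_b <- 1L
    lines <- c(lines, nt_at(1L, -10 * spacing, -10 * spacing, 50))
  }
  if (decoy_hydrogens) {
    nb <- setdiff(resolved, binding_positions)
    for (b in utils::head(nb, 3)) {
      lines <- c(lines, nt_at(resno_b, ca[b + 1, 1], ca[b + 1, 2], 4,
                              name = "H1", element = "H"))
    }
  }
  lines <- c(lines, "TER", "END")
  pdb_text <- paste(lines, collapse = "\n")

  # ground truth: resolved-residue indices (0-based over ATOM records)
  contact_resolved <- match(binding_positions, resolved) - 1L
  labels <- integer(n_residues)
  labels[binding_positions + 1L] <- 1L
  list(pdb_text = pdb_text,
       contacts = tibble::tibble(chain_id = rep("A", length(contact_resolved)),
                                 residue_index = contact_resolved),
       labels = labels, sequence = paste(seqv, collapse = ""),
       na_kind = na_kind, structure_id = structure_id)
}

#' Generate a synthetic multiple alignment with controlled conservation
#'
#' The first row (`query`) is the input sequence verbatim; in every other
#' row, conserved positions are copied unchanged and all remaining positions
#' are independently replaced with probability `mutation_rate` by a
#' different, uniformly chosen amino acid.
#'
#' @param seq Query sequence (string).
#' @param n_seqs Total number of rows, including the query.
#' @param conserved_positions 0-based positions copied verbatim in all rows.
#' @param mutation_rate Per-position substitution probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return Named character vector of aligned sequences (`query`, `seq2`,
#'   ...), writable with `Biostrings::writeXStringSet`.
#' @export
make_synthetic_msa <- function(seq, n_seqs, conserved_positions = integer(),
                               mutation_rate = 0.5, seed = 1) {
  stopifnot(mutation_rate >= 0, mutation_rate <= 1, n_seqs >= 1)
  q <- strsplit(seq, "")[[1]]
  L <- length(q)
  conserved <- conserved_positions + 1L
  if (length(conserved) && (min(conserved) < 1 || max(conserved) > L)) {
    stop("conserved_positions out of range", call. = FALSE)
  }
  free <- setdiff(seq_len(L), conserved)
  rows <- withr::with_seed(seed, {
    lapply(seq_len(n_seqs - 1), function(s) {
      r <- q
      mut <- free[stats::runif(length(free)) < mutation_rate]
      r[mut] <- vapply(r[mut], function(a) sample(setdiff(AA1, a), 1),
                       character(1))
      paste(r, collapse = "")
    })
  })
  out <- c(seq, unlist(rows))
  names(out) <- c("query", if (n_seqs > 1) paste0("seq", seq_len(n_seqs - 1) + 1))
  out
}

#' Generate a planted-signal two-stage benchmark dataset
#'
#' Simulates proteins of random sequence with per-residue descriptor tracks.
#' A fixed fraction are binders: each receives 1-3 contiguous binding
#' patches whose residues' conservation, relative accessibility and disorder
#' channels are shifted upward by `delta` channel standard deviations (the
#' planted effect); non-binders carry no patches. Entropy is kept
#' anti-correlated with conservation, as in real profiles. All randomness is
#' seeded; ground-truth labels are returned at both the residue and the
#' protein level.
#'
#' @param n_proteins Number of proteins (default 200).
#' @param fraction_binders Fraction labeled as binders (default 0.5).
#' @param length_range Chain length range (default 60-120).
#' @param n_patches_range Patches per binder (default 1-3).
#' @param patch_length_range Patch length range (default 5-15).
#' @param delta Effect size in channel SD units (default 2).
#' @param seed Integer seed.
#' @return An [na_dataset()] with singleton clusters; attributes `seed` and
#'   `delta` record the generating conditions.
#' @export
make_planted_dataset <- function(n_proteins = 200, fraction_binders = 0.5,
                                 length_range = c(60, 120),
                                 n_patches_range = c(1, 3),
                                 patch_length_range = c(5, 15),
                                 delta = 2, seed = 1) {
  stopifnot(fraction_binders > 0, fraction_binders < 1, delta >= 0)
  n_bind <- round(n_proteins * fraction_binders)
  protein_label <- c(rep(1L, n_bind), rep(0L, n_proteins - n_bind))
  sd_cons <- 0.15; sd_acc <- 0.15; sd_dis <- 0.12
  gen <- withr::with_seed(seed, {
    lapply(seq_len(n_proteins), function(p) {
      L <- sample(length_range[1]:length_range[2], 1)
      seqv <- paste(sample(AA1, L, replace = TRUE), collapse = "")
      labels <- integer(L)
      if (protein_label[p] == 1) {
        for (j in seq_len(sample(n_patches_range[1]:n_patches_range[2], 1))) {
          len <- sample(patch_length_range[1]:patch_length_range[2], 1)
          start <- sample(L - len + 1, 1)
          labels[start:(start + len - 1)] <- 1L
        }
      }
      shift <- delta * labels
      cons <- pmin(1, pmax(0, stats::rnorm(L, 0.45, sd_cons) + shift * sd_cons))
      ent <- pmax(0, (1 - cons) * log2(20) + stats::rnorm(L, 0, 0.1))
      ss <- matrix(stats::rgamma(3 * L, 1), ncol = 3)
      ss <- ss / rowSums(ss)
      acc <- pmin(1, pmax(0, stats::rnorm(L, 0.45, sd_acc) + shift * sd_acc))
      dis <- pmin(1, pmax(0, stats::rnorm(L, 0.35, sd_dis) + shift * sd_dis))
      tr <- track_set(cons, ent, sample(30:500, 1), ss[, 1], ss[, 2], ss[, 3],
                      acc, as.numeric(acc > 0.5), dis)
      list(sequence = seqv, labels = labels, tracks = tr)
    })
  })
  ds <- na_dataset(
    id = sprintf("prot%03d", seq_len(n_proteins)),
    sequence = vapply(gen, `[[`, character(1), "sequence"),
    labels = lapply(gen, `[[`, "labels"),
    tracks = lapply(gen, `[[`, "tracks"),
    protein_label = protein_label
  )
  attr(ds, "seed") <- seed
  attr(ds, "delta") <- delta
  ds
}
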