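# Parsing, chain classification, contact mapping and chain labeling.

minimal_pdb <- function() {
  paste(c(
    "ATOM      1  N   MET A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  MET A   1       1.400   0.000   0.000  1.00  0.00           C",
    "ATOM      3  N   ALA A   2       3.000   1.000   0.000  1.00  0.00           N",
    "ATOM      4  CA  ALA A   2       4.400   1.000   0.000  1.00  0.00           C",
    "TER", "END"), collapse = "\n")
}

test_that("parse_pdb builds ordered chains, residues and atoms", {
  m <- parse_pdb(minimal_pdb())
  expect_s3_class(m, "na_structure")
  expect_equal(nrow(m$chains), 1)
  expect_equal(m$chains$n_resolved, 2)
  expect_equal(m$chains$atom_sequence, "MA")
  # no SEQRES -> sequence reconstructed from ATOM records
  expect_equal(m$chains$seqres_sequence, "MA")
  expect_equal(sort(unique(m$atoms$residue_index)), c(0L, 1L))
})

test_that("SEQRES sequence is kept even when residues are unresolved", {
  toy <- make_toy_structure(10, binding_positions = 4, seed = 2,
                            unresolved_positions = c(1, 7))
  m <- parse_pdb(toy$pdb_text)
  prot <- m$chains[m$chains$kind == "protein", ]
  expect_equal(nchar(prot$seqres_sequence), 10)
  expect_equal(prot$n_resolved, 8)
  expect_equal(prot$seqres_sequence, toy$sequence)
})

test_that("hydrogens are flagged from the element column or atom name", {
  txt <- paste(c(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  H   GLY A   1       0.500   0.500   0.000  1.00  0.00           H",
    "ATOM      3 1HB  GLY A   1       0.700   0.100   0.000  1.00  0.00",
    "END"), collapse = "\n")
  m <- parse_pdb(txt)
  expect_equal(m$atoms$is_hydrogen, c(FALSE, TRUE, TRUE))
})

test_that("malformed coordinates raise an error naming the line", {
  bad <- sub("   1.400", "   1.4x0", minimal_pdb(), fixed = TRUE)
  expect_error(parse_pdb(bad), "line 2")
  expect_error(parse_pdb("REMARK nothing here"), "no ATOM")
})

test_that("chains are classified by residue-alphabet majority", {
  expect_equal(classify_chain(c("DA", "DC", "DG", "DT")), "DNA")
  expect_equal(classify_chain(c("A", "C", "G", "U")), "RNA")
  expect_equal(classify_chain(c("ALA", "GLY", "LYS")), "protein")
  expect_equal(classify_chain(c("HOH", "HOH", "ZN")), "other")
  expect_error(classify_chain(character()), "empty")
})

test_that("contact rule is strictly below the cutoff", {
  near <- paste(c(
    "ATOM      1  CB  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CB  GLY A   2      30.000   0.000   0.000  1.00  0.00           C",
    "TER",
    "ATOM      3  P    DA B   1       4.990   0.000   0.000  1.00  0.00           P",
    "ATOM      4  P    DC B   2      35.000   0.000   0.000  1.00  0.00           P",
    "END"), collapse = "\n")
  ct <- map_contacts(parse_pdb(near), 5, "DNA")
  expect_equal(ct$residue_index, 0L)  # 4.99 in, residue 2 at exactly 5.00 out
  exact <- sub("      35.000", "      25.000", near, fixed = TRUE)
  ct2 <- map_contacts(parse_pdb(exact), 5, "DNA")
  expect_equal(ct2$residue_index, 0L)  # second residue at exactly 5.0 from P
})

test_that("map_contacts equals the exhaustive all-pairs scan on random toys", {
  for (seed in 1:10) {
    spec_n <- 20 + seed
    bind <- sort(sample(0:(spec_n - 1), sample(0:4, 1)))
    toy <- make_toy_structure(spec_n, bind, seed = seed,
                              decoy_hydrogens = TRUE)
    m <- parse_pdb(toy$pdb_text)
    got <- map_contacts(m, 5, "DNA")
    expect_equal(got, brute_contacts(m, 5, "DNA"), info = paste("seed", seed))
    expect_equal(got$residue_index, toy$contacts$residue_index)
  }
})

test_that("contact set is invariant to chain/atom record order", {
  toy <- make_toy_structure(15, c(3, 11), seed = 5)
  lines <- strsplit(toy$pdb_text, "\n")[[1]]
  atom <- grepl("^ATOM", lines)
  prot <- atom & grepl(" A ", lines, fixed = TRUE)
  na <- atom & !prot
  reordered <- paste(c(lines[na], "TER", lines[prot], "TER", "END"),
                     collapse = "\n")
  expect_equal(map_contacts(parse_pdb(reordered), 5, "DNA")$residue_index,
               map_contacts(parse_pdb(toy$pdb_text), 5, "DNA")$residue_index)
})

test_that("label_chains keeps only contacting chains and marks contacts", {
  toy <- make_toy_structure(35, c(3, 7), seed = 4)
  # append a second, contact-free protein chain C far from the nucleic acid
  far <- vapply(1:3, function(i) {
    sprintf("ATOM  %5d  CA  GLY C%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
            900 + i, i, 500 + 10 * i, 500, 500)
  }, character(1))
  txt <- sub("\nEND", paste0("\n", paste(far, collapse = "\n"), "\nTER\nEND"),
             toy$pdb_text, fixed = TRUE)
  m <- parse_pdb(txt)
  expect_equal(sum(m$chains$kind == "protein"), 2)
  lc <- label_chains(m, map_contacts(m, 5, "DNA"), "DNA")
  expect_equal(nrow(lc), 1)
  expect_equal(lc$chain_id, "A")
  expect_equal(which(lc$labels[[1]] == 1) - 1L, c(3L, 7L))
  expect_true(all(vapply(lc$labels, sum, numeric(1)) >= 1))

  empty <- make_toy_structure(35, integer(), seed = 4)
  m2 <- parse_pdb(empty$pdb_text)
  lc2 <- label_chains(m2, map_contacts(m2, 5, "DNA"), "DNA")
  expect_equal(nrow(lc2), 0)
})

test_that("length and undetermined-residue filters behave at the boundary", {
  chains <- tibble::tibble(
    structure_id = "s", chain_id = c("A", "B", "C"),
    na_kind = "DNA",
    sequence = c(strrep("K", 29), strrep("K", 30),
                 paste0(strrep("K", 25), "X", strrep("K", 24))),
    labels = list(integer(29), integer(30), integer(50)),
    resolved = list(rep(TRUE, 29), rep(TRUE, 30), rep(TRUE, 50))
  )
  kept <- filter_sequences(chains)
  expect_equal(kept$chain_id, "B")
  expect_equal(filter_sequences(kept), kept)  # idempotent
  expect_equal(nrow(filter_sequences(chains[0, ])), 0)
})

test_that("full-to-structure alignment maps unresolved positions to NA", {
  expect_equal(align_full_to_structure("ACDEFG", "ACDEFG"), 0:5)
  # internal two-residue deletion
  mp <- align_full_to_structure("MKVLATREQW", "MKVATREQW")
  expect_equal(sum(is.na(mp)), 1)
  expect_true(all(diff(stats::na.omit(mp)) > 0))  # monotonic
  mp2 <- align_full_to_structure("ACDEFG", "ACDFG")
  expect_true(is.na(mp2[4]))  # E has no structure partner
  expect_equal(sum(!is.na(mp2)), 5)
  expect_error(align_full_to_structure("", "ACD"), "non-empty")
})

test_that("alignment scores match an independent affine-gap DP", {
  withr::with_seed(42, {
    for (i in 1:8) {
      a <- paste(sample(c("A","C","D","E","F","G","K","L"), 15, TRUE),
                 collapse = "")
      b <- paste(sample(c("A","C","D","E","F","G","K","L"),
                        sample(10:18, 1), TRUE), collapse = "")
      pa <- Biostrings::pairwiseAlignment(
        a, b, type = "global", substitutionMatrix = "BLOSUM62",
        gapOpening = 10, gapExtension = 0.5)
      expect_equal(Biostrings::score(pa), gotoh_score(a, b))
    }
  })
})

test_that("mask_unresolved clears labels and masks where unmapped", {
  toy <- make_toy_structure(40, c(5, 9), seed = 1)
  m <- parse_pdb(toy$pdb_text)
  lc <- label_chains(m, map_contacts(m, 5, "DNA"), "DNA")
  full_map <- seq_len(nchar(lc$sequence)) - 1L
  same <- mask_unresolved(lc, full_map)
  expect_true(all(same$resolved[[1]]))
  full_map[c(2, 30)] <- NA
  masked <- mask_unresolved(lc, full_map)
  expect_equal(sum(!masked$resolved[[1]]), 2)
  expect_equal(masked$labels[[1]][c(2, 30)], c(0L, 0L))
  expect_error(mask_unresolved(lc, full_map[-1]), "length")
})

test_that("a masked residue still contributes to its neighbours' windows", {
  toy <- make_toy_structure(40, c(5, 9), seed = 11)
  n <- nchar(toy$sequence)
  tr <- track_set(rep(0.5, n), rep(2, n), 50, rep(1, n), rep(0, n), rep(0, n),
                  rep(0.5, n), rep(1, n), rep(0.5, n))
  resolved <- rep(TRUE, n); resolved[11] <- FALSE
  fx <- featurize_chain(toy$sequence, tr, resolved = resolved)
  v11 <- fx$features[12, ]   # residue index 11; window covers masked index 10
  aa10 <- substr(toy$sequence, 11, 11)
  expect_equal(unname(v11[sprintf("aa_%s_o%+d", aa10, -1)]), 1)
  expect_false(fx$mask[11])
})
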