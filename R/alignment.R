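# Global pairwise alignment utilities: full-sequence-to-structure mapping and
# identity/coverage for redundancy clustering. All alignments are
# Needleman-Wunsch with BLOSUM62, gap open 10, gap extend 0.5 (the defaults
# of the EMBOSS Needle tool), via Biostrings.

nw_align <- function(a, b) {
  Biostrings::pairwiseAlignment(
    pattern = a, subject = b, type = "global",
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5
  )
}

#' Map full-sequence positions onto structure-resolved positions
#'
#' Globally aligns a full (e.g. SEQRES- or UniProt-derived) sequence to the
#' structure-resolved sequence and returns, for every full-sequence position,
#' the 0-based index of the matched structure residue, or `NA` where the
#' structure has a gap (an unresolved residue). The mapping is monotonic.
#'
#' @param full_seq Full protein sequence (string).
#' @param struct_seq Structure-resolved sequence (string).
#' @return Integer vector of length `nchar(full_seq)`; entries are 0-based
#'   structure indices or `NA`.
#' @examples
#' align_full_to_structure("ACDEFG", "ACDFG")
#' @export
align_full_to_structure <- function(full_seq, struct_seq) {
  if (!nzchar(full_seq) || !nzchar(struct_seq)) {
    stop("sequences must be non-empty", call. = FALSE)
  }
  pa <- nw_align(full_seq, struct_seq)
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  as <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  mapping <- rep(NA_integer_, nchar(full_seq))
  fi <- 0L; si <- 0L
  for (k in seq_along(ap)) {
    p_gap <- ap[k] == "-"
    s_gap <- as[k] == "-"
    if (!p_gap) fi <- fi + 1L
    if (!s_gap) si <- si + 1L
    if (!p_gap && !s_gap) mapping[fi] <- si - 1L
  }
  mapping
}

#' Pairwise sequence identity and coverage
#'
#' Computes a Needleman-Wunsch global alignment and reports identity
#' (identical aligned positions divided by the shorter sequence length, the
#' BLASTclust `-L`-on-shorter convention) and coverage (aligned positions
#' where neither sequence has a gap, divided by the shorter sequence length).
#'
#' @param a,b Protein sequences (strings).
#' @return One-row tibble with columns `identity` and `coverage`, both
#'   fractions in `[0, 1]`.
#' @examples
#' pairwise_identity("ACDEFGHIK", "ACDEFGHIV")
#' @export
pairwise_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty", call. = FALSE)
  pa <- nw_align(a, b)
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  both <- ap != "-" & as_ != "-"
  shorter <- min(nchar(a), nchar(b))
  tibble::tibble(
    identity = sum(both & ap == as_) / shorter,
    coverage = sum(both) / shorter
  )
}
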