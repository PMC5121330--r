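# Per-column conservation, entropy and alignment depth from an MSA.

#' Conservation, entropy and alignment depth from a multiple alignment
#'
#' For every column of the alignment at which the query row has a residue
#' (its ungapped positions define the chain coordinate system), computes the
#' amino-acid frequency distribution with a pseudocount of 1/20 per symbol
#' (gaps and non-standard letters excluded from the counts), Shannon entropy
#' in bits over the 20 amino acids, conservation `1 - entropy / log2(20)`,
#' and the alignment depth `n_align` (sequences with a non-gap at that
#' column).
#'
#' @param msa Named character vector of aligned sequences (equal lengths,
#'   `-` or `.` for gaps), or an `AAStringSet`/`AAMultipleAlignment`, or the
#'   path to an aligned FASTA file.
#' @param query Id (name) or 1-based row index of the query sequence.
#' @return Tibble with one row per query residue: `residue_index` (0-based),
#'   `conservation`, `entropy`, `n_align`.
#' @examples
#' msa <- make_synthetic_msa("MKVLAT", n_seqs = 20, conserved_positions = c(0, 3),
#'                           mutation_rate = 0.8, seed = 1)
#' conservation_from_msa(msa, "query")
#' @export
conservation_from_msa <- function(msa, query = 1) {
  if (inherits(msa, "AAMultipleAlignment")) msa <- as(msa, "AAStringSet")
  if (inherits(msa, "AAStringSet")) {
    msa <- stats::setNames(as.character(msa), names(msa))
  }
  if (is.character(msa) && length(msa) == 1 && file.exists(msa)) {
    ss <- Biostrings::readAAStringSet(msa)
    msa <- stats::setNames(as.character(ss), names(ss))
  }
  stopifnot(is.character(msa), length(msa) >= 1)
  if (length(unique(nchar(msa))) != 1) {
    stop("aligned sequences must have equal lengths", call. = FALSE)
  }
  if (is.character(query)) {
    qi <- match(query, names(msa))
    if (is.na(qi)) stop(sprintf("query '%s' not found in MSA", query), call. = FALSE)
  } else {
    qi <- as.integer(query)
    if (qi < 1 || qi > length(msa)) stop("query index out of range", call. = FALSE)
  }
  m <- do.call(rbind, strsplit(toupper(msa), ""))
  gap <- m == "-" | m == "."
  qcols <- which(!gap[qi, ])
  pseudo <- 1 / 20
  out <- lapply(qcols, function(j) {
    col <- m[!gap[, j], j]
    counts <- table(factor(col, levels = AA1))
    p <- (as.numeric(counts) + pseudo) / (sum(counts) + 20 * pseudo)
    h <- -sum(p * log2(p))
    tibble::tibble(entropy = h, conservation = 1 - h / log2(20),
                   n_align = sum(!gap[, j]))
  })
  res <- dplyr::bind_rows(out)
  tibble::tibble(residue_index = seq_along(qcols) - 1L,
                 conservation = pmax(0, res$conservation),
                 entropy = res$entropy, n_align = res$n_align)
}
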