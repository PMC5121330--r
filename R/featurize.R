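# Assembly of windowed per-residue feature vectors.

# n x dims matrix of raw channel values for every residue of the chain
channel_matrix <- function(channel, sequence, tracks) {
  n <- nchar(sequence)
  letters1 <- strsplit(sequence, "")[[1]]
  switch(channel,
    aa = {
      m <- matrix(0, n, 20, dimnames = list(NULL, AA1))
      hit <- match(letters1, AA1)
      ok <- !is.na(hit)
      m[cbind(which(ok), hit[ok])] <- 1
      m
    },
    conservation = cbind(tracks$conservation),
    entropy = cbind(tracks$entropy),
    n_align = cbind(log10(pmax(tracks$n_align, 1))),
    ss3 = cbind(tracks$ss_helix, tracks$ss_strand, tracks$ss_other),
    disorder = cbind(tracks$disorder),
    accessibility = cbind(tracks$acc_rel, tracks$acc_exposed),
    physchem = {
      tab <- aa_physchem_table()
      m <- matrix(0, n, 5)
      hit <- match(letters1, rownames(tab))
      ok <- !is.na(hit)
      m[ok, ] <- tab[hit[ok], , drop = FALSE]
      m
    },
    term_dist = cbind(pmin(seq_len(n) - 1L, n - seq_len(n)) / n),
    stop(sprintf("unknown channel '%s'", channel), call. = FALSE)
  )
}

#' Assemble the feature vector of one residue
#'
#' Concatenates, in schema order, each channel's per-residue values over its
#' centred window around residue `i`; window positions beyond the chain
#' termini take the channel's padding value (0, an all-zero one-hot for the
#' amino-acid channel).
#'
#' @param sequence Chain sequence (string).
#' @param tracks `na_tracks` for the chain.
#' @param schema An `na_schema`; default [default_feature_schema()].
#' @param i Residue index, 0-based.
#' @return Named numeric vector of length `schema_total(schema)`.
#' @export
assemble_vector <- function(sequence, tracks, schema = default_feature_schema(),
                            i) {
  n <- nchar(sequence)
  if (i < 0 || i >= n) {
    stop(sprintf("residue index %d out of range [0, %d)", i, n), call. = FALSE)
  }
  featurize_chain(sequence, tracks, schema)$features[i + 1L, ]
}

#' Feature matrix of a whole chain
#'
#' One assembled row per residue (including unresolved residues, which are
#' legitimate window neighbours); the row mask marks training-eligible
#' residues, i.e. those with `resolved = TRUE`.
#'
#' @param sequence Chain sequence (string).
#' @param tracks `na_tracks` matching the chain length.
#' @param schema An `na_schema`.
#' @param resolved Logical per-residue mask (default all `TRUE`).
#' @return List of class `na_features`: `features` (matrix
#'   `n x schema_total(schema)` with schema column names), `mask` (logical),
#'   `fingerprint` (hash of the column layout).
#' @export
featurize_chain <- function(sequence, tracks, schema = default_feature_schema(),
                            resolved = NULL) {
  n <- nchar(sequence)
  if (nrow(tracks) != n) {
    stop(sprintf("tracks have %d rows for a %d-residue chain", nrow(tracks), n),
         call. = FALSE)
  }
  if (is.null(resolved)) resolved <- rep(TRUE, n)
  stopifnot(length(resolved) == n)
  blocks <- lapply(seq_len(nrow(schema)), function(ci) {
    vals <- channel_matrix(schema$channel[ci], sequence, tracks)
    w <- schema$window[ci]
    pad <- schema$padding[ci]
    offs <- seq.int(-(w %/% 2), w %/% 2)
    do.call(cbind, lapply(offs, function(o) {
      src <- seq_len(n) + o
      ok <- src >= 1 & src <= n
      m <- matrix(pad, n, ncol(vals))
      m[ok, ] <- vals[src[ok], , drop = FALSE]
      m
    }))
  })
  X <- do.call(cbind, blocks)
  colnames(X) <- schema_colnames(schema)
  structure(list(features = X, mask = as.logical(resolved),
                 fingerprint = rlang::hash(colnames(X))),
            class = "na_features")
}

#' @export
print.na_features <- function(x, ...) {
  cat("<na_features> ", nrow(x$features), " residues x ", ncol(x$features),
      " features (", sum(x$mask), " training-eligible)\n", sep = "")
  invisible(x)
}
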