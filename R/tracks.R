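# Per-residue descriptor tracks: validated container plus TSV I/O.
#
# The tracks are consumed as inputs (conservation/entropy/depth from an MSA
# or a profile database; secondary structure, accessibility and disorder
# from external predictors); this package validates and windows them but
# never re-implements the predictors.

TRACK_COLS <- c("conservation", "entropy", "n_align", "ss_helix", "ss_strand",
                "ss_other", "acc_rel", "acc_exposed", "disorder")

#' Build a validated per-residue track set
#'
#' @param conservation Per-residue conservation in `[0, 1]`.
#' @param entropy Per-residue entropy in bits, `>= 0`.
#' @param n_align Alignment depth (`>= 1`); a single chain-level value is
#'   recycled.
#' @param ss_helix,ss_strand,ss_other Three-state secondary-structure
#'   probabilities; each residue's triple must sum to 1 within `[0.9, 1.1]`.
#' @param acc_rel Relative solvent accessibility in `[0, 1]`.
#' @param acc_exposed Buried/exposed flag, 0 or 1.
#' @param disorder Disorder propensity in `[0, 1]`.
#' @return Tibble of class `na_tracks` with a `residue_index` column
#'   (0-based) and the nine track columns.
#' @export
track_set <- function(conservation, entropy, n_align, ss_helix, ss_strand,
                      ss_other, acc_rel, acc_exposed, disorder) {
  n <- length(conservation)
  if (length(n_align) == 1) n_align <- rep(n_align, n)
  tr <- tibble::tibble(
    residue_index = seq_len(n) - 1L,
    conservation = as.numeric(conservation), entropy = as.numeric(entropy),
    n_align = as.numeric(n_align),
    ss_helix = as.numeric(ss_helix), ss_strand = as.numeric(ss_strand),
    ss_other = as.numeric(ss_other),
    acc_rel = as.numeric(acc_rel), acc_exposed = as.numeric(acc_exposed),
    disorder = as.numeric(disorder)
  )
  validate_tracks(tr)
}

validate_tracks <- function(tr) {
  n <- nrow(tr)
  lens <- vapply(tr[TRACK_COLS], length, integer(1))
  if (any(lens != n)) stop("all tracks must share the chain length", call. = FALSE)
  if (anyNA(tr[TRACK_COLS])) stop("tracks contain missing values", call. = FALSE)
  chk <- function(ok, what) {
    if (!all(ok)) {
      stop(sprintf("%s out of range at residue_index %s", what,
                   paste(tr$residue_index[!ok][1], collapse = ",")),
           call. = FALSE)
    }
  }
  chk(tr$conservation >= 0 & tr$conservation <= 1, "conservation")
  chk(tr$entropy >= 0, "entropy")
  chk(tr$n_align >= 1, "n_align")
  ss_sum <- tr$ss_helix + tr$ss_strand + tr$ss_other
  chk(tr$ss_helix >= 0 & tr$ss_strand >= 0 & tr$ss_other >= 0 &
        ss_sum >= 0.9 & ss_sum <= 1.1, "ss3 (simplex tolerance 0.9-1.1)")
  chk(tr$acc_rel >= 0 & tr$acc_rel <= 1, "acc_rel")
  chk(tr$acc_exposed %in% c(0, 1), "acc_exposed")
  chk(tr$disorder >= 0 & tr$disorder <= 1, "disorder")
  class(tr) <- c("na_tracks", setdiff(class(tr), "na_tracks"))
  tr
}

#' Load per-residue tracks from per-channel TSV files
#'
#' Expects one TSV per channel, each with a `residue_index` column followed
#' by the channel's value column(s): `profile` (conservation, entropy,
#' n_align), `ss3` (ss_helix, ss_strand, ss_other), `accessibility`
#' (acc_rel, acc_exposed) and `disorder` (disorder). Row counts must equal
#' the chain length; malformed or out-of-range entries are rejected with the
#' offending file named.
#'
#' @param files Named list or vector of paths with names `profile`, `ss3`,
#'   `accessibility`, `disorder`.
#' @param n_residues Expected chain length.
#' @return An `na_tracks` tibble.
#' @export
load_tracks <- function(files, n_residues) {
  need <- c("profile", "ss3", "accessibility", "disorder")
  if (!all(need %in% names(files))) {
    stop("files must be named: ", paste(need, collapse = ", "), call. = FALSE)
  }
  read_one <- function(path, cols) {
    x <- utils::read.delim(path, check.names = FALSE)
    if (nrow(x) != n_residues) {
      stop(sprintf("%s: %d rows for a %d-residue chain", path, nrow(x),
                   n_residues), call. = FALSE)
    }
    miss <- setdiff(c("residue_index", cols), names(x))
    if (length(miss)) {
      stop(sprintf("%s: missing column(s) %s", path,
                   paste(miss, collapse = ", ")), call. = FALSE)
    }
    for (cc in cols) {
      v <- suppressWarnings(as.numeric(x[[cc]]))
      if (anyNA(v)) {
        stop(sprintf("%s: non-numeric '%s' at row %d", path, cc,
                     which(is.na(v))[1]), call. = FALSE)
      }
      x[[cc]] <- v
    }
    x[order(x$residue_index), cols, drop = FALSE]
  }
  pr <- read_one(files[["profile"]], c("conservation", "entropy", "n_align"))
  ss <- read_one(files[["ss3"]], c("ss_helix", "ss_strand", "ss_other"))
  ac <- read_one(files[["accessibility"]], c("acc_rel", "acc_exposed"))
  di <- read_one(files[["disorder"]], "disorder")
  track_set(pr$conservation, pr$entropy, pr$n_align,
            ss$ss_helix, ss$ss_strand, ss$ss_other,
            ac$acc_rel, ac$acc_exposed, di$disorder)
}

#' Write a track set to per-channel TSV files
#'
#' Inverse of [load_tracks()]: writes `profile.tsv`, `ss3.tsv`,
#' `accessibility.tsv` and `disorder.tsv` under `dir`.
#'
#' @param tracks An `na_tracks` tibble.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths.
#' @export
write_tracks <- function(tracks, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(cols, name) {
    p <- file.path(dir, paste0(name, ".tsv"))
    utils::write.table(tracks[c("residue_index", cols)], p, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(
    profile = w(c("conservation", "entropy", "n_align"), "profile"),
    ss3 = w(c("ss_helix", "ss_strand", "ss_other"), "ss3"),
    accessibility = w(c("acc_rel", "acc_exposed"), "accessibility"),
    disorder = w("disorder", "disorder")
  )
  invisible(paths)
}
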