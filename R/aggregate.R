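# Aggregation of a per-residue score track into the 15 protein-level
# distribution features feeding the stage-2 classifier.

#' Within-protein Z-scores of a residue score track
#'
#' `Z_i = (s_i - mean(s)) / sd_pop(s)` with the population (divide-by-n)
#' standard deviation; a constant track (zero variance) yields all-zero Z.
#' Z-scores are computed per protein, never across a dataset: the features
#' describe each protein's internal score distribution.
#'
#' @param scores Numeric vector of per-residue scores in `[0, 1]`.
#' @return Numeric vector of Z-scores, same length.
#' @export
zscores <- function(scores) {
  stopifnot(length(scores) >= 1, all(scores >= 0 & scores <= 1))
  m <- mean(scores)
  s <- sqrt(mean((scores - m)^2))
  if (s == 0) return(rep(0, length(scores)))
  (scores - m) / s
}

#' Aggregate a residue score track into 15 protein-level features
#'
#' The features, in order: `f1` protein length; `f2` highest score;
#' `f3`-`f9` counts of residues with score strictly above 0.7, 0.6, 0.5,
#' 0.4, 0.3, 0.2, 0.1; `f10` count of the `n - 3` overlapping 4-residue
#' windows in which at least two residues score above 0.3 (0 when `n < 4`);
#' `f11`-`f14` counts of residues with within-protein Z-score strictly above
#' 3, 2, 1, 0.5; `f15` count with Z strictly below -2. "Above" is strict
#' throughout; `z_tail = "abs"` replaces `f11` by the two-sided count
#' `|Z| > 3`.
#'
#' @param scores Numeric per-residue scores in `[0, 1]`.
#' @param z_tail `"above"` (default) counts `Z > 3` in `f11`; `"abs"` counts
#'   `|Z| > 3`.
#' @return One-row tibble with columns `f1` ... `f15`.
#' @examples
#' aggregate_scores(c(0.8, 0.2, 0.35, 0.0))
#' @export
aggregate_scores <- function(scores, z_tail = c("above", "abs")) {
  z_tail <- match.arg(z_tail)
  stopifnot(length(scores) >= 1, all(scores >= 0 & scores <= 1))
  n <- length(scores)
  thr <- c(0.7, 0.6, 0.5, 0.4, 0.3, 0.2, 0.1)
  counts <- vapply(thr, function(t) sum(scores > t), numeric(1))
  f10 <- 0
  if (n >= 4) {
    hot <- scores > 0.3
    f10 <- sum(vapply(seq_len(n - 3), function(i) sum(hot[i:(i + 3)]) >= 2,
                      logical(1)))
  }
  z <- zscores(scores)
  f11 <- if (z_tail == "abs") sum(abs(z) > 3) else sum(z > 3)
  tibble::tibble(
    f1 = n, f2 = max(scores),
    f3 = counts[1], f4 = counts[2], f5 = counts[3], f6 = counts[4],
    f7 = counts[5], f8 = counts[6], f9 = counts[7],
    f10 = f10,
    f11 = f11, f12 = sum(z > 2), f13 = sum(z > 1), f14 = sum(z > 0.5),
    f15 = sum(z < -2)
  )
}

#' Aggregate score tracks for many proteins
#'
#' @param tracks Named list of per-residue score vectors, one per protein.
#' @param z_tail Passed to [aggregate_scores()].
#' @return Tibble with an `id` column followed by `f1` ... `f15`.
#' @export
aggregate_tracks <- function(tracks, z_tail = c("above", "abs")) {
  z_tail <- match.arg(z_tail)
  stopifnot(!is.null(names(tracks)))
  dplyr::bind_cols(
    tibble::tibble(id = names(tracks)),
    dplyr::bind_rows(lapply(tracks, aggregate_scores, z_tail = z_tail))
  )
}
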