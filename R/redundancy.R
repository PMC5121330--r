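# Redundancy clustering and homology-aware fold assignment.
#
# Sequences are clustered by greedy single-linkage on a global-alignment
# identity/coverage graph (a deterministic surrogate for BLASTclust with the
# same thresholds), and clusters -- never individual sequences -- are
# assigned to cross-validation folds, so homologous chains can never sit on
# both sides of a train/test split.

#' Cluster sequences by identity and coverage
#'
#' Single-linkage clustering: sequences are processed longest-first (ties
#' broken by id); each sequence links to every existing cluster in which any
#' member reaches both `identity_thr` and `coverage_thr` against it (via
#' [pairwise_identity()]); linked clusters are merged, and a sequence linking
#' nowhere founds a new cluster. The result equals the transitive closure of
#' the thresholded pair graph and is deterministic for a given input set
#' regardless of input order.
#'
#' @param seqs Named character vector of sequences; names are unique ids.
#' @param identity_thr Identity threshold, default 0.30.
#' @param coverage_thr Coverage threshold, default 0.50.
#' @return Tibble with columns `id`, `cluster_id` (integer, 1-based in
#'   founding order) and `representative` (logical, `TRUE` for the founder).
#' @export
cluster_sequences <- function(seqs, identity_thr = 0.30, coverage_thr = 0.50) {
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids))) stop("sequences must be named", call. = FALSE)
  if (anyDuplicated(ids)) stop("duplicate sequence ids", call. = FALSE)
  ord <- order(-nchar(seqs), ids)
  ids <- ids[ord]; seqs <- seqs[ord]
  members <- list()   # founding-order cluster -> character vector of ids
  for (i in seq_along(seqs)) {
    linked <- which(vapply(members, function(mm) {
      for (m in mm) {
        r <- pairwise_identity(seqs[[i]], seqs[[m]])
        if (r$identity >= identity_thr && r$coverage >= coverage_thr) {
          return(TRUE)
        }
      }
      FALSE
    }, logical(1)))
    if (length(linked) == 0) {
      members[[length(members) + 1]] <- ids[i]
    } else {
      # the new sequence may bridge several clusters; merge them all into
      # the earliest-founded one
      keep <- linked[1]
      members[[keep]] <- c(members[[keep]],
                           unlist(members[linked[-1]], use.names = FALSE),
                           ids[i])
      members[linked[-1]] <- NULL
    }
  }
  assign <- integer(length(ids))
  for (cl in seq_along(members)) assign[match(members[[cl]], ids)] <- cl
  reps <- vapply(members, function(m) m[1], character(1))
  tibble::tibble(id = ids, cluster_id = assign,
                 representative = ids == reps[assign])
}

#' Trivial one-sequence-per-cluster assignment
#'
#' Convenience for datasets known to be mutually non-redundant (e.g.
#' simulated random sequences), skipping the quadratic alignment pass.
#'
#' @param ids Character vector of unique sequence ids.
#' @return A cluster tibble as from [cluster_sequences()].
#' @export
singleton_clusters <- function(ids) {
  if (anyDuplicated(ids)) stop("duplicate sequence ids", call. = FALSE)
  tibble::tibble(id = as.character(ids), cluster_id = seq_along(ids),
                 representative = TRUE)
}

#' Assign clusters to cross-validation folds
#'
#' Clusters are shuffled by `seed`, then assigned one at a time to the fold
#' currently smallest by total residue count (sequence length), so folds are
#' balanced by the number of training examples. No cluster is ever split
#' across folds.
#'
#' @param clusters Cluster tibble from [cluster_sequences()].
#' @param k Number of folds (default 3).
#' @param seed Integer seed for the shuffle.
#' @param sizes Optional named numeric vector of per-id sizes (e.g. sequence
#'   lengths); defaults to 1 per sequence.
#' @return Tibble with columns `cluster_id` and `fold` (0-based).
#' @export
make_folds <- function(clusters, k = 3, seed = 1, sizes = NULL) {
  cl_ids <- unique(clusters$cluster_id)
  if (length(cl_ids) < k) {
    stop(sprintf("need at least %d clusters for %d folds, got %d",
                 k, k, length(cl_ids)), call. = FALSE)
  }
  if (is.null(sizes)) sizes <- stats::setNames(rep(1, nrow(clusters)), clusters$id)
  cl_size <- vapply(cl_ids, function(cl) {
    sum(sizes[clusters$id[clusters$cluster_id == cl]])
  }, numeric(1))
  ord <- withr::with_seed(seed, sample(seq_along(cl_ids)))
  fold_load <- numeric(k)
  fold_of <- integer(length(cl_ids))
  for (j in ord) {
    f <- which.min(fold_load)
    fold_of[j] <- f - 1L
    fold_load[f] <- fold_load[f] + cl_size[j]
  }
  tibble::tibble(cluster_id = cl_ids, fold = fold_of)
}
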