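# Grouped cross-validation of the full two-stage pipeline.

#' Assemble a dataset tibble for the two-stage pipeline
#'
#' @param id Character chain/protein ids (unique).
#' @param sequence Character sequences.
#' @param labels List of per-residue 0/1 label vectors.
#' @param tracks List of `na_tracks`, one per chain.
#' @param protein_label Binary per-protein labels (binder = 1).
#' @param resolved Optional list of per-residue logical masks (default all
#'   resolved).
#' @param cluster_id Optional cluster ids (default singleton clusters).
#' @return Tibble of class `na_dataset`.
#' @export
na_dataset <- function(id, sequence, labels, tracks, protein_label,
                       resolved = NULL, cluster_id = NULL) {
  if (anyDuplicated(id)) stop("duplicate ids", call. = FALSE)
  if (is.null(resolved)) resolved <- lapply(nchar(sequence), function(n) rep(TRUE, n))
  if (is.null(cluster_id)) cluster_id <- seq_along(id)
  ok <- mapply(function(s, l, r, tr) {
    nchar(s) == length(l) && nchar(s) == length(r) && nchar(s) == nrow(tr)
  }, sequence, labels, resolved, tracks)
  if (!all(ok)) {
    stop("sequence, labels, resolved and tracks lengths disagree for id(s): ",
         paste(id[!ok], collapse = ", "), call. = FALSE)
  }
  out <- tibble::tibble(id = as.character(id), sequence = sequence,
                        labels = labels, resolved = resolved, tracks = tracks,
                        protein_label = as.integer(protein_label),
                        cluster_id = as.integer(cluster_id))
  class(out) <- c("na_dataset", class(out))
  out
}

#' Two-stage grouped cross-validation
#'
#' Runs the full pipeline under homology-aware k-fold cross-validation:
#' stage-1 residue models are trained per fold on the training folds'
#' resolved residues and score only the held-out fold's chains; the
#' out-of-fold residue score tracks are aggregated into the 15 protein
#' features; stage-2 protein models are trained per fold on those features
#' and score only the held-out proteins. A chain scored by a model whose
#' training data included its own fold is a hard error.
#'
#' @param dataset An [na_dataset()].
#' @param folds Fold tibble from [make_folds()] over the dataset's clusters
#'   (default: computed with `k = 3` and `seed`).
#' @param schema Feature schema (default [default_feature_schema()]).
#' @param n_trees Trees per forest (default 1000).
#' @param seed Integer seed.
#' @param k Folds when `folds` is not supplied.
#' @param z_tail Passed to [aggregate_scores()].
#' @return Object of class `na_two_stage_cv`: residue and protein fold
#'   models, a `chains` tibble (id, fold, protein_label, out-of-fold
#'   `oof_scores` list-column), and a `proteins` tibble (id, fold, label,
#'   the 15 features, out-of-fold `oof_score`).
#' @export
cross_validate <- function(dataset, folds = NULL,
                           schema = default_feature_schema(),
                           n_trees = 1000, seed = 1, k = 3,
                           z_tail = c("above", "abs")) {
  z_tail <- match.arg(z_tail)
  stopifnot(inherits(dataset, "na_dataset"))
  clusters <- tibble::tibble(id = dataset$id, cluster_id = dataset$cluster_id)
  if (is.null(folds)) {
    sizes <- stats::setNames(nchar(dataset$sequence), dataset$id)
    folds <- make_folds(clusters, k = k, seed = seed, sizes = sizes)
  }
  k <- length(unique(folds$fold))
  chain_fold <- folds$fold[match(dataset$cluster_id, folds$cluster_id)]
  if (anyNA(chain_fold)) stop("folds do not cover every cluster", call. = FALSE)

  s1 <- cross_validate_residues(dataset, chain_fold, schema = schema,
                                n_trees = n_trees, seed = seed)
  n_chain <- nrow(dataset)
  oof_scores <- s1$oof_scores
  residue_models <- s1$models

  F <- aggregate_tracks(stats::setNames(oof_scores, dataset$id), z_tail = z_tail)
  Fmat <- protein_feature_matrix(F)
  protein_models <- vector("list", k)
  oof_protein <- numeric(n_chain)
  for (f in sort(unique(folds$fold))) {
    tr_idx <- which(chain_fold != f)
    te_idx <- which(chain_fold == f)
    pm <- train_protein_model(Fmat[tr_idx, , drop = FALSE],
                              dataset$protein_label[tr_idx],
                              n_trees = n_trees, seed = seed + 100 + f)
    protein_models[[f + 1L]] <- pm
    oof_protein[te_idx] <- predict_proteins(pm, Fmat[te_idx, , drop = FALSE])
  }

  chains <- tibble::tibble(id = dataset$id, fold = chain_fold,
                           protein_label = dataset$protein_label,
                           labels = dataset$labels,
                           resolved = dataset$resolved,
                           oof_scores = oof_scores)
  proteins <- dplyr::bind_cols(
    tibble::tibble(id = dataset$id, fold = chain_fold,
                   label = dataset$protein_label),
    F[grep("^f[0-9]+$", names(F), value = TRUE)],
    tibble::tibble(oof_score = oof_protein)
  )
  structure(list(residue_models = residue_models,
                 protein_models = protein_models,
                 chains = chains, proteins = proteins, k = k,
                 folds = folds, seed = seed, n_trees = n_trees),
            class = "na_two_stage_cv")
}

#' Stage-1 residue-model cross-validation
#'
#' Trains one residue model per fold on the other folds' resolved residues
#' and scores every chain of the held-out fold (all residues, resolved or
#' not, so the score track matches the sequence length). Raises a hard
#' error on any leakage of a chain into its own training fold.
#'
#' @param dataset An [na_dataset()].
#' @param chain_fold Integer fold per chain (0-based).
#' @param schema,n_trees,seed As in [cross_validate()].
#' @return List: `models` (one `na_residue_model` per fold), `oof_scores`
#'   (list of per-residue out-of-fold score vectors, dataset order).
#' @export
cross_validate_residues <- function(dataset, chain_fold,
                                    schema = default_feature_schema(),
                                    n_trees = 1000, seed = 1) {
  stopifnot(length(chain_fold) == nrow(dataset))
  feats <- mapply(function(s, tr, r) featurize_chain(s, tr, schema, r),
                  dataset$sequence, dataset$tracks, dataset$resolved,
                  SIMPLIFY = FALSE)
  fold_levels <- sort(unique(chain_fold))
  oof_scores <- vector("list", nrow(dataset))
  models <- vector("list", length(fold_levels))
  for (f in fold_levels) {
    tr_idx <- which(chain_fold != f)
    te_idx <- which(chain_fold == f)
    if (any(chain_fold[tr_idx] == f) || any(te_idx %in% tr_idx)) {
      stop("leakage: chain assigned to its own training fold", call. = FALSE)
    }
    if (length(tr_idx) == 0) {
      stop(sprintf("fold %d has no training chains", f), call. = FALSE)
    }
    Xtr <- do.call(rbind, lapply(tr_idx, function(i) {
      feats[[i]]$features[feats[[i]]$mask, , drop = FALSE]
    }))
    ytr <- unlist(lapply(tr_idx, function(i) {
      dataset$labels[[i]][feats[[i]]$mask]
    }))
    m <- train_residue_model(Xtr, ytr, n_trees = n_trees, seed = seed + f)
    models[[match(f, fold_levels)]] <- m
    for (i in te_idx) {
      oof_scores[[i]] <- predict_residues(m, feats[[i]]$features)
    }
  }
  list(models = models, oof_scores = oof_scores)
}

#' @export
print.na_two_stage_cv <- function(x, ...) {
  g <- glance(x)
  cat("<na_two_stage_cv> ", nrow(x$proteins), " proteins, ", x$k, " folds, ",
      x$n_trees, " trees\n", sep = "")
  cat(sprintf("  stage-1 out-of-fold ROC AUC %.3f | stage-2 %.3f\n",
              g$stage1_roc_auc, g$stage2_roc_auc))
  invisible(x)
}

# residue-level out-of-fold scores/labels over resolved residues
stage1_pooled <- function(x) {
  s <- unlist(mapply(function(sc, r) sc[r], x$chains$oof_scores,
                     x$chains$resolved, SIMPLIFY = FALSE))
  l <- unlist(mapply(function(lb, r) lb[r], x$chains$labels,
                     x$chains$resolved, SIMPLIFY = FALSE))
  list(scores = unname(s), labels = unname(l))
}

#' Per-protein out-of-fold results of a cross-validated pipeline
#' @param x An `na_two_stage_cv`.
#' @param ... Unused.
#' @return Tibble: `id`, `fold`, `label`, `f1`...`f15`, `oof_score`.
#' @method tidy na_two_stage_cv
#' @export
tidy.na_two_stage_cv <- function(x, ...) x$proteins

#' One-row performance summary of a cross-validated pipeline
#'
#' @param x An `na_two_stage_cv`.
#' @param ... Unused.
#' @return Tibble with residue- and protein-level out-of-fold ROC and PR
#'   AUCs and the positive-fraction random baselines.
#' @method glance na_two_stage_cv
#' @export
glance.na_two_stage_cv <- function(x, ...) {
  s1 <- stage1_pooled(x)
  tibble::tibble(
    n_proteins = nrow(x$proteins),
    n_residues = length(s1$labels),
    stage1_roc_auc = auc(roc_curve(s1$scores, s1$labels)),
    stage1_pr_auc = auc(pr_curve(s1$scores, s1$labels)),
    stage1_baseline = random_baseline(s1$labels),
    stage2_roc_auc = auc(roc_curve(x$proteins$oof_score, x$proteins$label)),
    stage2_pr_auc = auc(pr_curve(x$proteins$oof_score, x$proteins$label)),
    stage2_baseline = random_baseline(x$proteins$label)
  )
}

#' Predict a novel protein with the trained fold models
#'
#' Stage 1 averages the per-fold residue models' score tracks (the fold
#' combination is defined at the protein level only); stage 2 scores the
#' aggregated features with each protein fold model and combines them by the
#' two-of-three majority rule.
#'
#' @param sequence Protein sequence (string).
#' @param tracks `na_tracks` for the sequence.
#' @param residue_models List of fitted residue fold models.
#' @param protein_models List of exactly three fitted protein fold models.
#' @param schema Feature schema.
#' @param z_tail Passed to [aggregate_scores()].
#' @return List: `protein_score` (combined), `model_scores` (length 3),
#'   `residue_scores` (tibble `residue_index`, `score`), `features`
#'   (one-row tibble `f1`...`f15`).
#' @export
end_to_end_predict <- function(sequence, tracks, residue_models,
                               protein_models,
                               schema = default_feature_schema(),
                               z_tail = c("above", "abs")) {
  z_tail <- match.arg(z_tail)
  if (length(protein_models) != 3) {
    stop("exactly three protein fold models required", call. = FALSE)
  }
  X <- featurize_chain(sequence, tracks, schema)$features
  track <- rowMeans(vapply(residue_models, function(m) predict_residues(m, X),
                           numeric(nrow(X))))
  F <- aggregate_scores(track, z_tail = z_tail)
  ms <- vapply(protein_models, function(m) predict_proteins(m, F), numeric(1))
  list(protein_score = combine_majority(ms), model_scores = ms,
       residue_scores = tibble::tibble(residue_index = seq_len(nrow(X)) - 1L,
                                       score = track),
       features = F)
}
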