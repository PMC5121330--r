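# Stage-1 residue classifier, stage-2 protein classifier, grouped
# cross-validation and the two-of-three majority combination.
#
# Both stages are random-forest probability ensembles (default 1000 trees,
# feature subsampling sqrt(p), unlimited depth, no class weighting); scores
# are the ensemble's positive-class probability in [0, 1]. Fits are
# deterministic for a fixed seed (single-threaded ranger backend).

fit_rf <- function(X, y, n_trees, seed, mtry = NULL, model_class) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  y <- as.integer(y)
  if (length(unique(y)) < 2) {
    stop("training data contain a single class", call. = FALSE)
  }
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  fit <- ranger::ranger(
    x = X, y = factor(y, levels = c(0L, 1L)),
    num.trees = n_trees, mtry = mtry, probability = TRUE,
    importance = "impurity", seed = seed, num.threads = 1
  )
  structure(list(forest = fit, n_trees = n_trees, mtry = mtry, seed = seed,
                 fingerprint = rlang::hash(colnames(X)),
                 feature_names = colnames(X)),
            class = c(model_class, "na_model"))
}

rf_scores <- function(model, X) {
  stopifnot(inherits(model, "na_model"))
  if (!identical(rlang::hash(colnames(X)), model$fingerprint)) {
    stop("feature columns do not match the model's schema fingerprint",
         call. = FALSE)
  }
  p <- stats::predict(model$forest, data = X, num.threads = 1)$predictions
  unname(p[, "1"])
}

#' Train the per-residue binding-site classifier
#'
#' @param X Feature matrix (rows = residues, columns named by the schema).
#' @param y Binary residue labels (0/1).
#' @param n_trees Number of trees (default 1000).
#' @param seed Integer seed; fits are reproducible.
#' @param mtry Features sampled per split (default `floor(sqrt(p))`).
#' @return An `na_residue_model`.
#' @export
train_residue_model <- function(X, y, n_trees = 1000, seed = 1, mtry = NULL) {
  fit_rf(X, y, n_trees, seed, mtry, "na_residue_model")
}

#' Score residues with a trained residue model
#'
#' @param model An `na_residue_model`.
#' @param X Feature matrix with the model's schema columns (e.g.
#'   `featurize_chain(...)$features`).
#' @return Numeric score per row, in `[0, 1]`.
#' @export
predict_residues <- function(model, X) rf_scores(model, X)

#' Train the per-protein classifier on 15 aggregation features
#'
#' @param F Matrix or tibble of protein feature rows (`f1` ... `f15`).
#' @param y Binary protein labels (0/1).
#' @inheritParams train_residue_model
#' @return An `na_protein_model`.
#' @export
train_protein_model <- function(F, y, n_trees = 1000, seed = 1, mtry = NULL) {
  fit_rf(protein_feature_matrix(F), y, n_trees, seed, mtry, "na_protein_model")
}

#' Score proteins with a trained protein model
#' @param model An `na_protein_model`.
#' @param F Protein feature rows as in [train_protein_model()].
#' @return Numeric score per protein, in `[0, 1]`.
#' @export
predict_proteins <- function(model, F) rf_scores(model, protein_feature_matrix(F))

protein_feature_matrix <- function(F) {
  if (is.matrix(F)) return(F)
  F <- tibble::as_tibble(F)
  cols <- grep("^f[0-9]+$", names(F), value = TRUE)
  if (length(cols) == 0) stop("no f1...f15 feature columns found", call. = FALSE)
  as.matrix(F[cols])
}

#' Combine three fold-model scores by the two-of-three majority rule
#'
#' The combined score is the largest cutoff `t` at which at least two of the
#' three models still call the protein positive (score `>= t`); this equals
#' the median of the three scores, an equivalence verified by exhaustive
#' threshold sweep in the test suite.
#'
#' @param scores Numeric vector of exactly three scores in `[0, 1]`.
#' @return The combined score.
#' @examples
#' combine_majority(c(0.9, 0.5, 0.1))
#' @export
combine_majority <- function(scores) {
  if (length(scores) != 3) stop("exactly three model scores required", call. = FALSE)
  stopifnot(all(scores >= 0 & scores <= 1))
  stats::median(scores)
}

#' @export
print.na_model <- function(x, ...) {
  cat("<", class(x)[1], "> ", x$n_trees, " trees, mtry ", x$mtry,
      ", ", length(x$feature_names), " features, seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted model: per-feature importance
#' @param x An `na_model`.
#' @param ... Unused.
#' @return Tibble `feature`, `importance`, sorted decreasing.
#' @method tidy na_model
#' @export
tidy.na_model <- function(x, ...) {
  imp <- ranger::importance(x$forest)
  tibble::tibble(feature = names(imp), importance = unname(imp)) |>
    dplyr::arrange(dplyr::desc(.data$importance))
}

#' One-row model summary
#' @param x An `na_model`.
#' @param ... Unused.
#' @return Tibble: `n_trees`, `mtry`, `n_features`, `oob_error`.
#' @method glance na_model
#' @export
glance.na_model <- function(x, ...) {
  tibble::tibble(n_trees = x$n_trees, mtry = x$mtry,
                 n_features = length(x$feature_names),
                 oob_error = x$forest$prediction.error)
}
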