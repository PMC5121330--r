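# Residue / protein random-forest models, the majority combination and the
# cross-validated two-stage pipeline.

toy_matrix <- function(n, p, seed, shift = 0) {
  withr::with_seed(seed, {
    y <- rep(c(0L, 1L), length.out = n)
    X <- matrix(stats::rnorm(n * p), n, p,
                dimnames = list(NULL, paste0("x", seq_len(p))))
    X[y == 1, 1:3] <- X[y == 1, 1:3] + shift
    list(X = X, y = y)
  })
}

small_planted <- function(n = 24, delta = 2, seed = 3) {
  make_planted_dataset(n_proteins = n, delta = delta, seed = seed,
                       length_range = c(40, 60))
}

test_that("residue model training is deterministic and rejects one class", {
  d <- toy_matrix(80, 10, 1, shift = 2)
  m1 <- train_residue_model(d$X, d$y, n_trees = 60, seed = 5)
  m2 <- train_residue_model(d$X, d$y, n_trees = 60, seed = 5)
  expect_equal(predict_residues(m1, d$X), predict_residues(m2, d$X))
  m3 <- train_residue_model(d$X, d$y, n_trees = 60, seed = 6)
  expect_false(identical(predict_residues(m1, d$X), predict_residues(m3, d$X)))
  expect_error(train_residue_model(d$X, rep(1, 80), n_trees = 10), "single class")
})

test_that("residue scores are probabilities, pure, and schema-checked", {
  d <- toy_matrix(60, 8, 2, shift = 1)
  m <- train_residue_model(d$X, d$y, n_trees = 50, seed = 1)
  s <- predict_residues(m, d$X)
  expect_length(s, 60)
  expect_true(all(s >= 0 & s <= 1))
  dup <- d$X[c(7, 7), , drop = FALSE]
  sd2 <- predict_residues(m, dup)
  expect_equal(sd2[1], sd2[2])
  bad <- d$X
  colnames(bad)[1] <- "renamed"
  expect_error(predict_residues(m, bad), "fingerprint")
})

test_that("a separable protein feature set is learned perfectly", {
  F <- tibble::tibble(id = paste0("p", 1:40))
  for (k in 1:15) F[[paste0("f", k)]] <- 0
  y <- rep(c(0, 1), each = 20)
  F$f3 <- ifelse(y == 1, 30, 0)   # many high-scoring residues iff binder
  F$f2 <- ifelse(y == 1, 0.95, 0.2)
  m <- train_protein_model(F, y, n_trees = 100, seed = 2)
  expect_equal(as.numeric(predict_proteins(m, F) > 0.5), y)
})

test_that("label permutation collapses protein AUC to chance", {
  withr::with_seed(11, {
    n <- 150
    F <- tibble::as_tibble(stats::setNames(
      as.data.frame(matrix(stats::rnorm(n * 15), n, 15)), paste0("f", 1:15)))
    y <- sample(rep(c(0L, 1L), length.out = n))
    fold <- rep(0:2, length.out = n)
    oof <- numeric(n)
    for (f in 0:2) {
      m <- train_protein_model(F[fold != f, ], y[fold != f],
                               n_trees = 100, seed = 20 + f)
      oof[fold == f] <- predict_proteins(m, F[fold == f, ])
    }
    a <- auc(roc_curve(oof, y))
    expect_gte(a, 0.40)
    expect_lte(a, 0.60)
  })
})

test_that("the majority combination equals median and the sweep oracle", {
  expect_equal(combine_majority(c(0.9, 0.5, 0.1)), 0.5)
  expect_equal(combine_majority(c(0.4, 0.4, 0.4)), 0.4)
  expect_equal(combine_majority(c(1, 1, 0)), 1)
  expect_error(combine_majority(c(0.5, 0.5)), "three")
  withr::with_seed(8, {
    for (i in 1:200) {
      s <- round(stats::runif(3), 3)
      cm <- combine_majority(s)
      expect_equal(cm, stats::median(s))
      expect_equal(cm, sweep_majority(s), tolerance = 1e-9)
    }
  })
})

test_that("cross-validation yields one model per fold and out-of-fold scores", {
  ds <- small_planted()
  cv <- cross_validate(ds, n_trees = 40, seed = 2)
  expect_length(cv$residue_models, 3)
  expect_length(cv$protein_models, 3)
  expect_equal(sort(unique(cv$chains$fold)), 0:2)
  expect_equal(nrow(cv$proteins), nrow(ds))
  expect_true(all(vapply(cv$chains$oof_scores, length, integer(1)) ==
                    nchar(ds$sequence)))
  expect_true(all(unlist(cv$chains$oof_scores) >= 0 &
                    unlist(cv$chains$oof_scores) <= 1))
  g <- glance(cv)
  expect_true(all(c("stage1_roc_auc", "stage2_roc_auc") %in% names(g)))
  td <- tidy(cv)
  expect_true(all(paste0("f", 1:15) %in% names(td)))
})

test_that("shuffling held-out labels never changes the training-fold models", {
  ds <- small_planted()
  cv <- cross_validate(ds, n_trees = 40, seed = 9)
  # permute the labels of every fold-0 chain; models scoring fold 0 are
  # trained on folds 1 and 2 only, so fold-0 scores must be identical
  ds2 <- ds
  idx0 <- which(cv$chains$fold == 0)
  ds2$labels[idx0] <- lapply(ds2$labels[idx0], sample)
  ds2$protein_label[idx0] <- 1L - ds2$protein_label[idx0]
  # protein labels must keep both classes in every training split
  cv2 <- cross_validate(ds2, folds = cv$folds, n_trees = 40, seed = 9)
  expect_equal(cv$chains$oof_scores[idx0], cv2$chains$oof_scores[idx0])
})

test_that("leakage in a hand-built fold map is refused", {
  ds <- small_planted(n = 9)
  expect_error(
    cross_validate_residues(ds, chain_fold = rep(0L, 9), n_trees = 10),
    "leakage|no training chains"
  )
})

test_that("end-to-end prediction returns combined and per-residue output", {
  ds <- small_planted(n = 18, seed = 5)
  cv <- cross_validate(ds, n_trees = 40, seed = 4)
  q <- make_planted_dataset(n_proteins = 2, delta = 2, seed = 99,
                            length_range = c(40, 60))
  pred <- end_to_end_predict(q$sequence[1], q$tracks[[1]],
                             cv$residue_models, cv$protein_models)
  expect_gte(pred$protein_score, 0)
  expect_lte(pred$protein_score, 1)
  expect_equal(pred$protein_score, stats::median(pred$model_scores))
  expect_equal(nrow(pred$residue_scores), nchar(q$sequence[1]))
  expect_equal(ncol(pred$features), 15)
  expect_error(end_to_end_predict(q$sequence[1], q$tracks[[1]],
                                  cv$residue_models, cv$protein_models[1:2]),
               "three")
})

test_that("raising every residue score weakly raises the count features", {
  s <- rand_track(60, 17)
  up <- pmin(1, s + 0.15)
  f <- aggregate_scores(s); fu <- aggregate_scores(up)
  for (k in paste0("f", 3:9)) expect_gte(fu[[k]], f[[k]])
  expect_gte(fu$f2, f$f2)
})
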