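# Independent brute-force / closed-form oracles used to verify the
# implementation. These deliberately share no code with the package
# internals: naive loops and textbook dynamic programming only.

# exhaustive all-pairs heavy-atom distance scan over a parsed structure
brute_contacts <- function(model, cutoff = 5, na_kind = "DNA") {
  at <- model$atoms
  prot <- model$chains$chain_id[model$chains$kind == "protein"]
  nac <- model$chains$chain_id[model$chains$kind == na_kind]
  pa <- at[at$chain_id %in% prot & !at$is_hydrogen, ]
  qa <- at[at$chain_id %in% nac & !at$is_hydrogen, ]
  hits <- list()
  for (i in seq_len(nrow(pa))) {
    for (j in seq_len(nrow(qa))) {
      d <- sqrt((pa$x[i] - qa$x[j])^2 + (pa$y[i] - qa$y[j])^2 +
                  (pa$z[i] - qa$z[j])^2)
      if (d < cutoff) {
        hits[[length(hits) + 1]] <- c(pa$chain_id[i], pa$residue_index[i])
      }
    }
  }
  if (length(hits) == 0) {
    return(tibble::tibble(chain_id = character(), residue_index = integer()))
  }
  df <- unique(data.frame(chain_id = vapply(hits, `[`, "", 1),
                          residue_index = as.integer(vapply(hits, `[`, "", 2))))
  tibble::as_tibble(df[order(df$chain_id, df$residue_index), ])
}

# Gotoh affine-gap global alignment score (BLOSUM62, open 10, extend 0.5);
# returns only the optimal score
gotoh_score <- function(a, b, open = 10, ext = 0.5) {
  sub <- get_blosum62()
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); Ix <- M; Iy <- M
  # a gap of length L costs open + ext * L
  M[1, 1] <- 0
  for (i in 2:(n + 1)) Ix[i, 1] <- -open - (i - 1) * ext
  for (j in 2:(m + 1)) Iy[1, j] <- -open - (j - 1) * ext
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- sub[A[i - 1], B[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1]) + s
      Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext)
      Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext)
    }
  }
  max(M[n + 1, m + 1], Ix[n + 1, m + 1], Iy[n + 1, m + 1])
}

get_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# single-linkage transitive closure over the thresholded identity graph
closure_clusters <- function(seqs, id_thr = 0.30, cov_thr = 0.50) {
  n <- length(seqs)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j) {
        r <- pairwise_identity(seqs[[i]], seqs[[j]])
        adj[i, j] <- adj[j, i] <- r$identity >= id_thr && r$coverage >= cov_thr
      }
    }
  }
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (adj[i, j] && comp[j] != comp[i]) {
        comp[comp == comp[j]] <- comp[i]
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  stats::setNames(match(comp, unique(comp)), names(seqs))
}

# direct Shannon entropy (bits) of an amino-acid column with pseudocount 1/20
column_entropy_oracle <- function(letters1) {
  aa <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
  counts <- sapply(aa, function(a) sum(letters1 == a))
  p <- (counts + 1 / 20) / (sum(counts) + 1)
  -sum(p * log2(p))
}

# brute-force enumeration of the 15 aggregation features
brute_aggregate <- function(s) {
  n <- length(s)
  m <- mean(s); sd_pop <- sqrt(sum((s - m)^2) / n)
  z <- if (sd_pop == 0) rep(0, n) else (s - m) / sd_pop
  f10 <- 0
  if (n >= 4) {
    for (i in 1:(n - 3)) {
      if (sum(s[i:(i + 3)] > 0.3) >= 2) f10 <- f10 + 1
    }
  }
  c(f1 = n, f2 = max(s),
    f3 = sum(s > 0.7), f4 = sum(s > 0.6), f5 = sum(s > 0.5),
    f6 = sum(s > 0.4), f7 = sum(s > 0.3), f8 = sum(s > 0.2),
    f9 = sum(s > 0.1), f10 = f10,
    f11 = sum(z > 3), f12 = sum(z > 2), f13 = sum(z > 1),
    f14 = sum(z > 0.5), f15 = sum(z < -2))
}

# naive per-example confusion recount
brute_confusion <- function(scores, labels, cutoff) {
  tp <- fp <- tn <- fn <- 0
  for (i in seq_along(scores)) {
    pred <- scores[i] > cutoff
    if (pred && labels[i] == 1) tp <- tp + 1
    else if (pred && labels[i] == 0) fp <- fp + 1
    else if (!pred && labels[i] == 0) tn <- tn + 1
    else fn <- fn + 1
  }
  list(TP = tp, FP = fp, TN = tn, FN = fn)
}

# naive evaluation of the printed metric formulas, 0/0 -> 0
brute_metrics <- function(cf) {
  sdiv <- function(a, b) if (b == 0) 0 else a / b
  tp <- cf$TP; fp <- cf$FP; tn <- cf$TN; fn <- cf$FN
  den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  list(precision = sdiv(tp, tp + fp), recall = sdiv(tp, tp + fn),
       specificity = sdiv(tn, tn + fp), fpr = sdiv(fp, fp + tn),
       acc = (tp + tn) / (tp + fp + tn + fn),
       mcc = sdiv(tp * tn - fp * fn, den))
}

# exhaustive threshold sweep for the two-of-three majority rule: the largest
# cutoff t at which at least two scores are >= t
sweep_majority <- function(scores) {
  cand <- sort(unique(c(scores, seq(0, 1, by = 0.001))))
  best <- 0
  for (t in cand) if (sum(scores >= t) >= 2) best <- t
  best
}

# random seeded track in [0,1]
rand_track <- function(n, seed) {
  withr::with_seed(seed, stats::runif(n))
}
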