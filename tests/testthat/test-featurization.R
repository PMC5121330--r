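# MSA-derived profile tracks, track validation, schema and window assembly.

const_tracks <- function(n, cons = 0.5, ent = 2, depth = 50, dis = 0.5,
                         acc = 0.5) {
  track_set(rep(cons, n), rep(ent, n), depth, rep(1, n), rep(0, n),
            rep(0, n), rep(acc, n), rep(1, n), rep(dis, n))
}

rand_tracks <- function(n, seed) {
  withr::with_seed(seed, {
    ss <- matrix(stats::rgamma(3 * n, 1), ncol = 3); ss <- ss / rowSums(ss)
    track_set(stats::runif(n), stats::runif(n, 0, 4), sample(10:200, 1),
              ss[, 1], ss[, 2], ss[, 3], stats::runif(n),
              stats::rbinom(n, 1, 0.5), stats::runif(n))
  })
}

rand_chain <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A","C","D","E","G","K","L","R"),
                                      n, TRUE), collapse = ""))
}

test_that("column conservation and entropy behave at the limits", {
  # 50 identical residues: near-zero entropy, conservation near 1
  msa <- rep(paste(rep("K", 10), collapse = ""), 50)
  names(msa) <- c("query", paste0("seq", 2:50))
  pr <- conservation_from_msa(msa, "query")
  expect_true(all(pr$entropy < 0.25))
  expect_true(all(pr$conservation > 0.9))
  expect_equal(pr$n_align, rep(50L, 10))

  # column uniform over all 20 amino acids: maximum entropy, conservation 0
  aa <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")
  msa2 <- stats::setNames(aa, c("query", paste0("seq", 2:20)))
  pr2 <- conservation_from_msa(msa2, "query")
  expect_equal(pr2$entropy, log2(20), tolerance = 1e-10)
  expect_equal(pr2$conservation, 0, tolerance = 1e-10)
})

test_that("a half-A half-C column approaches one bit of entropy", {
  n <- 500
  msa <- stats::setNames(c(rep("A", n / 2), rep("C", n / 2)),
                         c("query", paste0("s", 2:n)))
  pr <- conservation_from_msa(msa, 1)
  expect_equal(pr$entropy, 1, tolerance = 0.05)
  expect_equal(pr$conservation, 1 - 1 / log2(20), tolerance = 0.02)
  # agreement with the direct-entropy oracle, including the pseudocount
  expect_equal(pr$entropy, column_entropy_oracle(unname(msa)), tolerance = 1e-12)
})

test_that("gap columns are excluded from counts and the query defines coordinates", {
  msa <- c(query = "AK-V", s2 = "AC-V", s3 = "A--V")
  pr <- conservation_from_msa(msa, "query")
  expect_equal(nrow(pr), 3)            # query has 3 ungapped positions
  expect_equal(pr$n_align, c(3L, 2L, 3L))
  expect_error(conservation_from_msa(msa, "nope"), "not found")
})

test_that("track TSV round trip validates lengths, types and ranges", {
  tr <- rand_tracks(30, 4)
  d <- withr::local_tempdir()
  write_tracks(tr, d)
  files <- list(profile = file.path(d, "profile.tsv"),
                ss3 = file.path(d, "ss3.tsv"),
                accessibility = file.path(d, "accessibility.tsv"),
                disorder = file.path(d, "disorder.tsv"))
  tr2 <- load_tracks(files, 30)
  expect_equal(as.data.frame(tr2), as.data.frame(tr), tolerance = 1e-12)
  expect_error(load_tracks(files, 29), "rows")
  # corrupt the ss3 simplex
  ss <- utils::read.delim(files$ss3)
  ss[3, 2:4] <- 0.2
  utils::write.table(ss, files$ss3, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_tracks(files, 30), "simplex")
  ss[3, 2] <- "oops"
  utils::write.table(ss, files$ss3, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_tracks(files, 30), "non-numeric")
})

test_that("the default schema totals 246 and survives YAML round trip", {
  sch <- default_feature_schema()
  expect_equal(schema_total(sch), 246L)
  expect_equal(sum(sch$dims * sch$window), 246)
  expect_true(all(sch$window %% 2 == 1))
  expect_equal(length(schema_colnames(sch)), 246)
  p <- withr::local_tempfile(fileext = ".yaml")
  write_feature_schema(sch, p)
  expect_equal(schema_total(read_feature_schema(p)), 246L)
  shipped <- system.file("extdata", "feature_schema.yaml", package = "nabind")
  expect_equal(schema_total(read_feature_schema(shipped)), 246L)
  expect_error(feature_schema(tibble::tibble(channel = "x", dims = 1,
                                             window = 4, padding = 0)),
               "odd")
})

test_that("assembled vectors have schema length everywhere, with zero padding", {
  n <- 50
  seqv <- rand_chain(n, 1)
  tr <- rand_tracks(n, 2)
  for (i in c(0, 1, 3, 25, n - 1)) {
    v <- assemble_vector(seqv, tr, i = i)
    expect_length(v, 246)
    expect_false(anyNA(v))
  }
  v0 <- assemble_vector(seqv, tr, i = 0)
  left <- grepl("_o-", names(v0), fixed = TRUE)
  expect_true(all(v0[left] == 0))  # everything left of centre is padding
  expect_error(assemble_vector(seqv, tr, i = n), "out of range")
})

test_that("windows are channel-local: ss3/disorder span 7, profile spans 9", {
  n <- 40
  seqv <- rand_chain(n, 3)
  tr <- rand_tracks(n, 5)
  i <- 20
  v <- assemble_vector(seqv, tr, i = i)
  ss_cols <- sprintf("ss3_%s_o%+d", rep(c("helix", "strand", "other"), 7),
                     rep(-3:3, each = 3))
  expect_equal(unname(v[ss_cols]),
               as.vector(t(cbind(tr$ss_helix, tr$ss_strand,
                                 tr$ss_other)[i + 1 + (-3:3), ])))
  expect_equal(unname(v[sprintf("disorder_v_o%+d", -3:3)]),
               tr$disorder[i + 1 + (-3:3)])
  expect_equal(unname(v[sprintf("conservation_v_o%+d", -4:4)]),
               tr$conservation[i + 1 + (-4:4)])
  expect_equal(unname(v[sprintf("entropy_v_o%+d", -4:4)]),
               tr$entropy[i + 1 + (-4:4)])
  # aa one-hot spans 9 and encodes the actual neighbours
  lets <- strsplit(seqv, "")[[1]]
  for (o in -4:4) {
    expect_equal(unname(v[sprintf("aa_%s_o%+d", lets[i + 1 + o], o)]), 1)
  }
})

test_that("featurize_chain masks unresolved rows and is channel-separable", {
  n <- 30
  seqv <- rand_chain(n, 7)
  tr <- rand_tracks(n, 8)
  resolved <- rep(TRUE, n); resolved[c(4, 18)] <- FALSE
  fx <- featurize_chain(seqv, tr, resolved = resolved)
  expect_equal(dim(fx$features), c(30L, 246L))
  expect_equal(sum(!fx$mask), 2)
  # rows equal assemble_vector at every index
  for (i in c(0, 14, 29)) {
    expect_equal(fx$features[i + 1, ], assemble_vector(seqv, tr, i = i))
  }
  # shifting one track changes only that channel's columns
  tr2 <- tr
  tr2$disorder <- pmin(1, tr$disorder + 0.1)
  fx2 <- featurize_chain(seqv, tr2, resolved = resolved)
  changed <- which(colSums(fx2$features != fx$features) > 0)
  expect_true(all(grepl("^disorder_", colnames(fx$features)[changed])))
})
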