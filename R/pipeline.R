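# Dataset construction from structures, the annotation keyword filter for
# negative sets, the end-to-end pipeline runner, and the subcommand
# dispatcher behind the thin command-line script.

#' Default negative-set keyword list
#'
#' Annotation terms whose presence disqualifies a protein from the negative
#' (non-binder) set: nucleic-acid binding terms, their GO ids, and the
#' cellular processes that imply binding. A documented stand-in list;
#' fully user-replaceable.
#'
#' @return Character vector of terms.
#' @export
default_keyword_terms <- function() {
  c("DNA binding", "RNA binding", "GO:0003677", "GO:0003723",
    "transcription", "replication", "recombination", "repair",
    "nucleic acid", "nuclease", "polymerase", "helicase", "nucleosome",
    "ribosom")
}

#' Filter candidate negatives by annotation keywords
#'
#' Case-insensitive substring match of each term against every non-id column
#' of the annotation table; an entry matching at least one term is removed.
#'
#' @param annotations Tibble/data frame with an `id` column plus free-text
#'   annotation columns, or the path to such a TSV.
#' @param terms Terms to screen for (default [default_keyword_terms()]); an
#'   empty list retains everything.
#' @param report Optional path: writes a TSV of removed ids with the first
#'   matching term.
#' @return Character vector of retained ids.
#' @export
keyword_filter <- function(annotations, terms = default_keyword_terms(),
                           report = NULL) {
  if (is.character(annotations) && length(annotations) == 1) {
    annotations <- utils::read.delim(annotations, check.names = FALSE,
                                     colClasses = "character")
  }
  annotations <- tibble::as_tibble(annotations)
  if (!"id" %in% names(annotations)) stop("annotations need an 'id' column", call. = FALSE)
  if (anyDuplicated(annotations$id)) stop("duplicate annotation ids", call. = FALSE)
  text_cols <- setdiff(names(annotations), "id")
  blob <- do.call(paste, c(annotations[text_cols], sep = " \r "))
  matched_term <- rep(NA_character_, nrow(annotations))
  for (term in terms) {
    hit <- is.na(matched_term) & grepl(term, blob, ignore.case = TRUE, fixed = FALSE)
    matched_term[hit] <- term
  }
  removed <- !is.na(matched_term)
  if (!is.null(report)) {
    utils::write.table(
      tibble::tibble(id = annotations$id[removed], term = matched_term[removed]),
      report, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  annotations$id[!removed]
}

#' Build a labeled dataset from co-complex structures
#'
#' Runs the structure stage over a set of PDB texts or files: parse, map
#' contacts (strict < `cutoff` Angstrom, hydrogens excluded), label chains,
#' drop contact-free chains, and apply the length / undetermined-residue
#' filter. Counts at every filter step are recorded in the `filter_log`
#' attribute.
#'
#' @param pdb_inputs Character vector of PDB texts or file paths, optionally
#'   named by structure id.
#' @param na_kind `"DNA"` or `"RNA"`.
#' @param cutoff Contact cutoff in Angstrom (default 5).
#' @param min_len Minimum chain length (default 30).
#' @return An `na_labeled_chains` tibble with a `filter_log` attribute
#'   (tibble of step, n).
#' @export
build_dataset <- function(pdb_inputs, na_kind = c("DNA", "RNA"), cutoff = 5,
                          min_len = 30) {
  na_kind <- match.arg(na_kind)
  ids <- names(pdb_inputs)
  if (is.null(ids)) ids <- sprintf("struct%03d", seq_along(pdb_inputs))
  labeled <- dplyr::bind_rows(lapply(seq_along(pdb_inputs), function(i) {
    model <- parse_pdb(pdb_inputs[[i]], structure_id = ids[i])
    contacts <- map_contacts(model, cutoff, na_kind)
    label_chains(model, contacts, na_kind)
  }))
  n_labeled <- nrow(labeled)
  kept <- filter_sequences(labeled, min_len = min_len)
  attr(kept, "filter_log") <- tibble::tibble(
    step = c("structures", "chains_with_contacts", "after_length_X_filter"),
    n = c(length(pdb_inputs), n_labeled, nrow(kept))
  )
  kept
}

#' Run the full two-stage pipeline and write its artifacts
#'
#' Executes featurize -> stage-1 grouped CV -> aggregate -> stage-2 grouped
#' CV -> evaluate on an assembled dataset and writes plain-text artifacts
#' under `out_dir`: per-protein out-of-fold scores and features
#' (`proteins.tsv`), pooled residue-level and protein-level metric tables
#' (`residue_metrics.tsv`, `protein_metrics.tsv`), ROC/PRC points
#' (`*_curve.tsv`), a performance summary (`summary.tsv`) and a manifest
#' JSON with the seed, tree count and a config hash.
#'
#' @param dataset An [na_dataset()].
#' @param out_dir Output directory.
#' @param n_trees,seed,k,schema,z_tail Passed to [cross_validate()].
#' @return The `na_two_stage_cv` object, invisibly; artifacts on disk.
#' @export
run_pipeline <- function(dataset, out_dir, n_trees = 1000, seed = 1, k = 3,
                         schema = default_feature_schema(),
                         z_tail = c("above", "abs")) {
  z_tail <- match.arg(z_tail)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cv <- cross_validate(dataset, schema = schema, n_trees = n_trees,
                       seed = seed, k = k, z_tail = z_tail)
  wtsv <- function(x, name) {
    utils::write.table(x, file.path(out_dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wtsv(tidy(cv), "proteins.tsv")
  s1 <- stage1_pooled(cv)
  wtsv(metrics_by_cutoff(s1$scores, s1$labels), "residue_metrics.tsv")
  wtsv(metrics_by_cutoff(cv$proteins$oof_score, cv$proteins$label),
       "protein_metrics.tsv")
  wtsv(roc_curve(s1$scores, s1$labels), "residue_roc_curve.tsv")
  wtsv(pr_curve(s1$scores, s1$labels), "residue_pr_curve.tsv")
  wtsv(roc_curve(cv$proteins$oof_score, cv$proteins$label),
       "protein_roc_curve.tsv")
  wtsv(pr_curve(cv$proteins$oof_score, cv$proteins$label),
       "protein_pr_curve.tsv")
  wtsv(glance(cv), "summary.tsv")
  manifest <- list(
    seed = seed, n_trees = n_trees, k = k, z_tail = z_tail,
    n_proteins = nrow(dataset), n_residues = sum(nchar(dataset$sequence)),
    config_hash = rlang::hash(list(seed, n_trees, k, z_tail,
                                   schema_colnames(schema)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(cv)
}

# ---- dataset directory I/O (used by the subcommands) -----------------------

#' Write / read a dataset directory
#'
#' Plain-text on-disk form of an [na_dataset()]: `sequences.fasta`,
#' `chains.tsv` (id, residue_index, label, resolved), per-chain track TSVs
#' under `tracks/<id>/`, `proteins.tsv` (id, protein_label, cluster_id) and
#' a `manifest.json`.
#'
#' @param dataset An [na_dataset()].
#' @param dir Directory to create.
#' @return `write_dataset_dir()` returns `dir` invisibly;
#'   `read_dataset_dir()` returns the reconstructed [na_dataset()].
#' @export
write_dataset_dir <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  seqs <- Biostrings::AAStringSet(stats::setNames(dataset$sequence, dataset$id))
  Biostrings::writeXStringSet(seqs, file.path(dir, "sequences.fasta"))
  chains <- dplyr::bind_rows(lapply(seq_len(nrow(dataset)), function(i) {
    tibble::tibble(id = dataset$id[i],
                   residue_index = seq_along(dataset$labels[[i]]) - 1L,
                   label = dataset$labels[[i]],
                   resolved = as.integer(dataset$resolved[[i]]))
  }))
  utils::write.table(chains, file.path(dir, "chains.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (i in seq_len(nrow(dataset))) {
    write_tracks(dataset$tracks[[i]], file.path(dir, "tracks", dataset$id[i]))
  }
  utils::write.table(
    tibble::tibble(id = dataset$id, protein_label = dataset$protein_label,
                   cluster_id = dataset$cluster_id),
    file.path(dir, "proteins.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(n_proteins = nrow(dataset),
                            seed = attr(dataset, "seed"),
                            delta = attr(dataset, "delta")),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_dataset_dir
#' @export
read_dataset_dir <- function(dir) {
  seqs <- Biostrings::readAAStringSet(file.path(dir, "sequences.fasta"))
  ids <- names(seqs)
  chains <- utils::read.delim(file.path(dir, "chains.tsv"))
  prot <- utils::read.delim(file.path(dir, "proteins.tsv"))
  labels <- lapply(ids, function(i) chains$label[chains$id == i])
  resolved <- lapply(ids, function(i) as.logical(chains$resolved[chains$id == i]))
  tracks <- lapply(ids, function(i) {
    base <- file.path(dir, "tracks", i)
    load_tracks(list(profile = file.path(base, "profile.tsv"),
                     ss3 = file.path(base, "ss3.tsv"),
                     accessibility = file.path(base, "accessibility.tsv"),
                     disorder = file.path(base, "disorder.tsv")),
                n_residues = length(labels[[match(i, ids)]]))
  })
  na_dataset(id = ids, sequence = unname(as.character(seqs)), labels = labels,
             tracks = tracks,
             protein_label = prot$protein_label[match(ids, prot$id)],
             resolved = resolved,
             cluster_id = prot$cluster_id[match(ids, prot$id)])
}

# ---- command-line dispatch -------------------------------------------------

cli_args <- function(args) {
  vals <- list()
  i <- 1
  while (i <= length(args)) {
    if (!startsWith(args[i], "--")) stop("unexpected argument: ", args[i], call. = FALSE)
    vals[[substring(args[i], 3)]] <- args[i + 1]
    i <- i + 2
  }
  vals
}

cli_schema <- function(opts) {
  if (is.null(opts[["schema"]])) default_feature_schema()
  else read_feature_schema(opts[["schema"]])
}

cli_get <- function(opts, name, default = NULL) {
  if (!is.null(opts[[name]])) opts[[name]]
  else if (!is.null(default)) default
  else stop("missing required option --", name, call. = FALSE)
}

#' Command-line interface dispatcher
#'
#' Subcommands: `simulate` (write a planted dataset directory),
#' `build-dataset` (PDB directory -> labeled chains TSV + FASTA),
#' `featurize`, `train-residue`, `aggregate`, `train-protein`, `predict`
#' and `evaluate` (the full cross-validated run of [run_pipeline()]). Every
#' subcommand takes `--out-dir` and `--seed`; see the package script
#' `inst/scripts/nabind` for shell usage.
#'
#' @param args Character vector, e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return Invisibly, the subcommand's main result.
#' @export
nabind_cli <- function(args) {
  if (length(args) == 0) {
    stop("usage: nabind <simulate|build-dataset|evaluate|predict|...> [--opt value]",
         call. = FALSE)
  }
  cmd <- args[1]
  opts <- cli_args(args[-1])
  out_dir <- cli_get(opts, "out-dir", ".")
  seed <- as.integer(cli_get(opts, "seed", "1"))
  switch(cmd,
    "simulate" = {
      ds <- make_planted_dataset(
        n_proteins = as.integer(cli_get(opts, "n-proteins", "200")),
        delta = as.numeric(cli_get(opts, "delta", "2")), seed = seed)
      write_dataset_dir(ds, out_dir)
      message("wrote planted dataset to ", out_dir)
      invisible(ds)
    },
    "build-dataset" = {
      files <- list.files(cli_get(opts, "pdb-dir"), pattern = "\\.pdb$",
                          full.names = TRUE)
      names(files) <- sub("\\.pdb$", "", basename(files))
      chains <- build_dataset(files, na_kind = cli_get(opts, "na-kind", "DNA"),
                              min_len = as.integer(cli_get(opts, "min-len", "30")))
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      flat <- dplyr::bind_rows(lapply(seq_len(nrow(chains)), function(i) {
        tibble::tibble(structure_id = chains$structure_id[i],
                       chain_id = chains$chain_id[i],
                       residue_index = seq_along(chains$labels[[i]]) - 1L,
                       one_letter = strsplit(chains$sequence[i], "")[[1]],
                       label = chains$labels[[i]],
                       resolved = as.integer(chains$resolved[[i]]))
      }))
      utils::write.table(flat, file.path(out_dir, "labels.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      ss <- Biostrings::AAStringSet(stats::setNames(
        chains$sequence, paste(chains$structure_id, chains$chain_id, sep = "_")))
      Biostrings::writeXStringSet(ss, file.path(out_dir, "sequences.fasta"))
      print(attr(chains, "filter_log"))
      invisible(chains)
    },
    "featurize" = {
      ds <- read_dataset_dir(cli_get(opts, "dataset-dir"))
      schema <- cli_schema(opts)
      dir.create(file.path(out_dir, "features"), recursive = TRUE,
                 showWarnings = FALSE)
      for (i in seq_len(nrow(ds))) {
        fx <- featurize_chain(ds$sequence[i], ds$tracks[[i]], schema,
                              ds$resolved[[i]])
        utils::write.table(
          cbind(residue_index = seq_len(nrow(fx$features)) - 1L,
                training_eligible = as.integer(fx$mask), fx$features),
          file.path(out_dir, "features", paste0(ds$id[i], ".tsv")),
          sep = "\t", quote = FALSE, row.names = FALSE)
      }
      message("wrote feature matrices for ", nrow(ds), " chains")
      invisible(NULL)
    },
    "train-residue" = {
      ds <- read_dataset_dir(cli_get(opts, "dataset-dir"))
      folds <- make_folds(tibble::tibble(id = ds$id, cluster_id = ds$cluster_id),
                          k = as.integer(cli_get(opts, "k", "3")), seed = seed,
                          sizes = stats::setNames(nchar(ds$sequence), ds$id))
      chain_fold <- folds$fold[match(ds$cluster_id, folds$cluster_id)]
      s1 <- cross_validate_residues(
        ds, chain_fold, schema = cli_schema(opts),
        n_trees = as.integer(cli_get(opts, "n-trees", "1000")), seed = seed)
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      saveRDS(s1$models, file.path(out_dir, "residue_models.rds"))
      scores <- dplyr::bind_rows(lapply(seq_len(nrow(ds)), function(i) {
        tibble::tibble(id = ds$id[i],
                       residue_index = seq_along(s1$oof_scores[[i]]) - 1L,
                       score = s1$oof_scores[[i]], fold = chain_fold[i])
      }))
      utils::write.table(scores, file.path(out_dir, "residue_scores.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      invisible(s1)
    },
    "aggregate" = {
      scores <- utils::read.delim(cli_get(opts, "scores"))
      tracks <- split(scores$score, scores$id)
      F <- aggregate_tracks(tracks)
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      utils::write.table(F, file.path(out_dir, "protein_features.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      invisible(F)
    },
    "train-protein" = {
      F <- utils::read.delim(cli_get(opts, "features"))
      lab <- utils::read.delim(cli_get(opts, "labels"))
      y <- lab$protein_label[match(F$id, lab$id)]
      m <- train_protein_model(
        F, y, n_trees = as.integer(cli_get(opts, "n-trees", "1000")),
        seed = seed)
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      saveRDS(m, file.path(out_dir, "protein_model.rds"))
      invisible(m)
    },
    "predict" = {
      ds <- read_dataset_dir(cli_get(opts, "dataset-dir"))
      rm_ <- readRDS(file.path(cli_get(opts, "models-dir"), "residue_models.rds"))
      pm <- readRDS(file.path(cli_get(opts, "models-dir"), "protein_models.rds"))
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      preds <- dplyr::bind_rows(lapply(seq_len(nrow(ds)), function(i) {
        pr <- end_to_end_predict(ds$sequence[i], ds$tracks[[i]], rm_, pm,
                                 schema = cli_schema(opts))
        tibble::tibble(id = ds$id[i], combined_score = pr$protein_score,
                       model1 = pr$model_scores[1], model2 = pr$model_scores[2],
                       model3 = pr$model_scores[3])
      }))
      utils::write.table(preds, file.path(out_dir, "predictions.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      invisible(preds)
    },
    "evaluate" = {
      ds <- read_dataset_dir(cli_get(opts, "dataset-dir"))
      cv <- run_pipeline(ds, out_dir,
                         n_trees = as.integer(cli_get(opts, "n-trees", "1000")),
                         seed = seed, schema = cli_schema(opts))
      saveRDS(cv$residue_models, file.path(out_dir, "residue_models.rds"))
      saveRDS(cv$protein_models, file.path(out_dir, "protein_models.rds"))
      print(glance(cv))
      invisible(cv)
    },
    stop(sprintf("unknown subcommand '%s'", cmd), call. = FALSE)
  )
}
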