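# Stage runners behind the command-line interface. Each reads its inputs from
# files, runs the corresponding module functions, writes artifacts into
# `outdir` and emits a JSON manifest. All stages are deterministic given
# identical inputs and seed.

require_inputs <- function(paths) {
  missing <- paths[!file.exists(paths)]
  if (length(missing) > 0) {
    rlang::abort(
      sprintf("missing input file(s): %s", paste(missing, collapse = ", ")),
      class = "cpipred_missing_input"
    )
  }
  invisible(TRUE)
}

#' Run the simulation stage: write a synthetic benchmark to disk
#'
#' @param outdir Output directory.
#' @param cfg A [generator_config()].
#' @return Invisibly, the list of written paths.
#' @export
run_simulate <- function(outdir, cfg = generator_config()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- make_benchmark_fixture(cfg, outdir)
  bench <- paths$benchmark
  write_manifest(outdir, "simulate",
                 counts = list(compounds = nrow(bench$compounds),
                               proteins = nrow(bench$proteins),
                               records = nrow(bench$records)),
                 extra = list(seed = cfg$seed))
  invisible(paths)
}

#' Run the curation stage
#'
#' @param records_path,compounds_path Input files (see [read_bioactivity()],
#'   [read_compounds()]).
#' @param outdir Output directory.
#' @param cfg A [curation_config()].
#' @return Invisibly, the `cpi_curation` object.
#' @export
run_curate <- function(records_path, compounds_path, outdir,
                       cfg = curation_config()) {
  require_inputs(c(records_path, compounds_path))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  records <- read_bioactivity(records_path)
  compounds <- read_compounds(compounds_path)
  cur <- curate_dataset(records, compounds, cfg)
  write_pairs(cur$pairs, file.path(outdir, "pairs.tsv"))
  jsonlite::write_json(cur$report, file.path(outdir, "curation-report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest(outdir, "curate",
                 counts = list(records = nrow(records),
                               pairs = nrow(cur$pairs)),
                 inputs = c(records_path, compounds_path),
                 extra = list(seed = cfg$seed))
  invisible(cur)
}

#' Run the correlation-space negative screen
#'
#' Builds descriptor tables, fits the correlation space on the curated
#' positives and screens the curated negatives; rejected negatives are
#' removed from the dataset.
#'
#' @param pairs_path Curated pairs TSV.
#' @param compounds_path,proteins_path Input entity files.
#' @param outdir Output directory.
#' @param n_components Canonical components. Default 5.
#' @return Invisibly, the screening report tibble.
#' @export
run_screen <- function(pairs_path, compounds_path, proteins_path, outdir,
                       n_components = 5) {
  require_inputs(c(pairs_path, compounds_path, proteins_path))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  pairs <- read_pairs(pairs_path)
  compounds <- read_compounds(compounds_path)
  proteins <- read_proteins(proteins_path)
  cdesc <- compound_descriptors(compounds)
  pdesc <- protein_descriptors(proteins)
  pos <- dplyr::filter(pairs, .data$label == "positive")
  neg <- dplyr::filter(pairs, .data$label == "negative")
  scr <- screen_negatives(neg, pos, cdesc, pdesc, n_components = n_components)
  readr::write_tsv(scr, file.path(outdir, "screen-report.tsv"), progress = FALSE)
  kept <- dplyr::bind_rows(pos,
                           dplyr::filter(scr, .data$verdict != "rejected") |>
                             dplyr::select(dplyr::all_of(names(pairs))))
  write_pairs(kept, file.path(outdir, "pairs-screened.tsv"))
  write_manifest(outdir, "screen",
                 counts = list(candidates = nrow(neg),
                               retained = sum(scr$verdict == "retained"),
                               rejected = sum(scr$verdict == "rejected"),
                               unscreened = sum(scr$verdict == "unscreened")),
                 inputs = c(pairs_path, compounds_path, proteins_path))
  invisible(scr)
}

#' Run the featurization stage
#'
#' Splits the curated pairs into train/test, fits the compound PCA on
#' training-set fingerprints and the 3-mer CBOW model on training-set
#' proteins only (no leakage), embeds everything and writes the pair feature
#' matrices, the protein embeddings and the fitted models.
#'
#' @param pairs_path Curated (possibly screened) pairs TSV.
#' @param compounds_path,proteins_path Input entity files.
#' @param outdir Output directory.
#' @param cur_cfg A [curation_config()] (train fraction + seed).
#' @param word_cfg A [word_model_config()].
#' @param n_compound_pcs Compound principal components. Default 200.
#' @return Invisibly, a list with the split, fitted models and matrices.
#' @export
run_featurize <- function(pairs_path, compounds_path, proteins_path, outdir,
                          cur_cfg = curation_config(),
                          word_cfg = word_model_config(),
                          n_compound_pcs = 200) {
  require_inputs(c(pairs_path, compounds_path, proteins_path))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  pairs <- read_pairs(pairs_path)
  compounds <- read_compounds(compounds_path)
  proteins <- read_proteins(proteins_path)

  split <- split_dataset(pairs, cur_cfg)
  feats <- featurize_split(split, compounds, proteins,
                           word_cfg = word_cfg,
                           n_compound_pcs = n_compound_pcs)

  write_pairs(split$train, file.path(outdir, "pairs-train.tsv"))
  write_pairs(split$test, file.path(outdir, "pairs-test.tsv"))
  write_feature_matrix(split$train, feats$train, file.path(outdir, "features-train.tsv.gz"))
  write_feature_matrix(split$test, feats$test, file.path(outdir, "features-test.tsv.gz"))
  emb_tbl <- function(m) {
    dplyr::bind_cols(
      tibble::tibble(protein_id = rownames(m) %||% character(0)),
      tibble::as_tibble(m, .name_repair = "minimal")
    )
  }
  readr::write_tsv(emb_tbl(feats$train_embeddings),
                   file.path(outdir, "protein-embeddings-train.tsv"), progress = FALSE)
  readr::write_tsv(emb_tbl(feats$test_embeddings),
                   file.path(outdir, "protein-embeddings-test.tsv"), progress = FALSE)
  saveRDS(feats$pca, file.path(outdir, "compound-pca.rds"))
  saveRDS(feats$word_model, file.path(outdir, "word-model.rds"))
  jsonlite::write_json(
    list(word_config = unclass(word_cfg), n_compound_pcs = feats$pca$n_components,
         checksum_pca = unname(tools::md5sum(file.path(outdir, "compound-pca.rds"))),
         checksum_word = unname(tools::md5sum(file.path(outdir, "word-model.rds")))),
    file.path(outdir, "feature-models.json"), auto_unbox = TRUE, digits = NA)
  write_manifest(outdir, "featurize",
                 counts = list(train_pairs = nrow(split$train),
                               test_pairs = nrow(split$test)),
                 inputs = c(pairs_path, compounds_path, proteins_path),
                 extra = list(seed = cur_cfg$seed))
  invisible(c(list(split = split), feats))
}

# Fit feature models on the training split and transform both splits.
featurize_split <- function(split, compounds, proteins,
                            word_cfg = word_model_config(),
                            n_compound_pcs = 200) {
  train_cids <- unique(split$train$compound_id)
  train_pids <- unique(split$train$protein_id)
  comp_map <- stats::setNames(compounds$fingerprint, compounds$compound_id)

  pca <- fit_compound_pca(comp_map[train_cids], n = n_compound_pcs)
  all_cids <- unique(c(split$train$compound_id, split$test$compound_id))
  comp_scores <- predict(pca, comp_map[all_cids])

  train_prot <- dplyr::filter(proteins, .data$protein_id %in% train_pids)
  corpus <- lapply(train_prot$sequence, tokenize_protein)
  wm <- train_word_model(corpus, word_cfg)
  all_prot <- dplyr::filter(
    proteins, .data$protein_id %in% unique(c(train_pids, split$test$protein_id)))
  emb <- embed_proteins(all_prot, wm)

  train <- build_pair_matrix(split$train, comp_scores, emb)
  test <- build_pair_matrix(split$test, comp_scores, emb)
  list(pca = pca, word_model = wm,
       train = train, test = test,
       train_embeddings = emb[rownames(emb) %in% train_pids, , drop = FALSE],
       test_embeddings = emb[rownames(emb) %in% setdiff(split$test$protein_id, train_pids), ,
                             drop = FALSE])
}

write_feature_matrix <- function(pairs, built, path) {
  tbl <- dplyr::bind_cols(
    pairs[c("compound_id", "protein_id", "label")],
    tibble::as_tibble(built$x, .name_repair = ~ paste0("f", seq_along(.x)))
  )
  readr::write_tsv(tbl, path, progress = FALSE)
  invisible(path)
}

read_feature_matrix <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  fcols <- grep("^f\\d+$", names(tbl))
  x <- as.matrix(tbl[, fcols])
  rownames(x) <- paste(tbl$compound_id, tbl$protein_id, sep = "|")
  list(x = x, y = as.integer(tbl$label == "positive"),
       pairs = tbl[c("compound_id", "protein_id", "label")])
}

#' Run the training stage
#'
#' @param features_dir Directory produced by [run_featurize()].
#' @param outdir Output directory.
#' @param spec A [network_spec()]; its `input_dim` is overridden by the
#'   feature matrix width.
#' @return Invisibly, the trained `cpi_dnn`.
#' @export
run_train <- function(features_dir, outdir, spec = network_spec()) {
  train_path <- file.path(features_dir, "features-train.tsv.gz")
  require_inputs(train_path)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tr <- read_feature_matrix(train_path)
  spec$input_dim <- ncol(tr$x)
  fit <- train_network(tr$x, tr$y, spec)
  saveRDS(fit, file.path(outdir, "model.rds"))
  jsonlite::write_json(unclass(spec), file.path(outdir, "architecture.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  readr::write_csv(fit$history, file.path(outdir, "training-history.csv"),
                   progress = FALSE)
  write_manifest(outdir, "train",
                 counts = list(train_pairs = nrow(tr$x)),
                 inputs = train_path,
                 extra = list(seed = spec$seed))
  invisible(fit)
}

#' Run the evaluation stage
#'
#' @param model_dir Directory produced by [run_train()].
#' @param features_dir Directory produced by [run_featurize()].
#' @param outdir Output directory.
#' @return Invisibly, the one-row metrics tibble.
#' @export
run_evaluate <- function(model_dir, features_dir, outdir) {
  model_path <- file.path(model_dir, "model.rds")
  test_path <- file.path(features_dir, "features-test.tsv.gz")
  require_inputs(c(model_path, test_path))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fit <- readRDS(model_path)
  te <- read_feature_matrix(test_path)
  pr <- predict(fit, te$x)
  pred <- dplyr::bind_cols(te$pairs, dplyr::rename(pr, predicted = "label"))
  readr::write_tsv(pred, file.path(outdir, "predictions.tsv"), progress = FALSE)
  metrics <- evaluate_predictions(te$y, pr$prob)
  jsonlite::write_json(as.list(metrics), file.path(outdir, "metrics.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_manifest(outdir, "evaluate",
                 counts = list(test_pairs = nrow(te$x)),
                 inputs = c(model_path, test_path))
  invisible(metrics)
}

#' Run the applicability-domain stage
#'
#' Computes each test protein's nearest-training-embedding distance, the
#' within-domain verdict at the critical distance, and distance-binned
#' performance of the evaluation predictions.
#'
#' @param eval_dir Directory produced by [run_evaluate()].
#' @param features_dir Directory produced by [run_featurize()].
#' @param outdir Output directory.
#' @param threshold Critical distance. Default 0.4.
#' @param edges Bin edges for [binned_performance()].
#' @return Invisibly, a list with the verdict table and the bin report.
#' @export
run_domain <- function(eval_dir, features_dir, outdir, threshold = 0.4,
                       edges = c(0, 0.4, 0.67, 1, 2, 3, 4, 10)) {
  pred_path <- file.path(eval_dir, "predictions.tsv")
  tr_emb_path <- file.path(features_dir, "protein-embeddings-train.tsv")
  te_emb_path <- file.path(features_dir, "protein-embeddings-test.tsv")
  require_inputs(c(pred_path, tr_emb_path, te_emb_path))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

  read_emb <- function(p) {
    tbl <- readr::read_tsv(p, show_col_types = FALSE, progress = FALSE)
    m <- as.matrix(tbl[, -1])
    rownames(m) <- tbl$protein_id
    m
  }
  tr_emb <- read_emb(tr_emb_path)
  te_emb <- read_emb(te_emb_path)
  pred <- readr::read_tsv(pred_path, show_col_types = FALSE, progress = FALSE)

  # test-split proteins also present in training have distance 0 by definition
  all_emb <- rbind(tr_emb, te_emb)
  prot_ids <- unique(pred$protein_id)
  nd <- nearest_training_distance(all_emb[prot_ids, , drop = FALSE], tr_emb)
  verdicts <- within_domain(nd$distance, threshold, protein_id = nd$protein_id) |>
    dplyr::mutate(nearest_id = nd$nearest_id, .after = "protein_id")
  readr::write_tsv(verdicts, file.path(outdir, "applicability.tsv"), progress = FALSE)

  dist_map <- stats::setNames(nd$distance, nd$protein_id)
  bins <- binned_performance(
    as.integer(pred$label == "positive"), pred$prob,
    unname(dist_map[pred$protein_id]), edges = edges
  )
  readr::write_tsv(bins, file.path(outdir, "bin-report.tsv"), progress = FALSE)
  write_manifest(outdir, "domain",
                 counts = list(proteins = nrow(verdicts),
                               within_domain = sum(verdicts$within_domain)),
                 inputs = c(pred_path, tr_emb_path, te_emb_path))
  invisible(list(verdicts = verdicts, bins = bins))
}
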