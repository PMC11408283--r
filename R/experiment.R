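# Canonical desk-scale experiments over a synthetic benchmark. These wire the
# stages together in memory: curation -> split -> featurization -> training ->
# evaluation, and the external applicability analysis on top of a fitted
# experiment.

#' Run the full pipeline on a synthetic benchmark
#'
#' Curates the benchmark's raw records, splits 80/20, fits the compound PCA
#' and the 3-mer CBOW model on the training split only, trains the classifier
#' and evaluates on the held-out split. Optionally repeats training with
#' permuted labels as a negative control: a model trained on shuffled labels
#' must not beat chance on the held-out data.
#'
#' @param bench A [generate_benchmark()] result.
#' @param cur_cfg A [curation_config()] (seed drives the split).
#' @param word_cfg A [word_model_config()].
#' @param spec A [network_spec()] (input_dim is set from the features).
#' @param n_compound_pcs Compound principal components. Default 200.
#' @param permuted_control Also train on permuted labels. Default FALSE.
#' @return List of class `cpi_experiment`: `curation`, `split`, `features`,
#'   `fit`, `predictions`, `metrics` and (optionally) `permuted_auroc`.
#' @export
benchmark_experiment <- function(bench,
                                 cur_cfg = curation_config(seed = bench$config$seed),
                                 word_cfg = word_model_config(epochs = 10,
                                                              seed = bench$config$seed),
                                 spec = network_spec(h1 = 256, h2 = 128,
                                                     dropout = 0.2,
                                                     learning_rate = 1e-3,
                                                     epochs = 30,
                                                     batch_size = 512,
                                                     seed = bench$config$seed),
                                 n_compound_pcs = 200,
                                 permuted_control = FALSE) {
  cur <- curate_dataset(bench$records, bench$compounds, cur_cfg,
                        nbits = bench$config$nbits)
  split <- split_dataset(cur$pairs, cur_cfg)
  feats <- featurize_split(split, bench$compounds, bench$proteins,
                           word_cfg = word_cfg,
                           n_compound_pcs = n_compound_pcs)
  spec$input_dim <- ncol(feats$train$x)
  fit <- train_network(feats$train$x, feats$train$y, spec)
  pr <- predict(fit, feats$test$x)
  metrics <- evaluate_predictions(feats$test$y, pr$prob)

  out <- list(curation = cur, split = split, features = feats, fit = fit,
              predictions = dplyr::bind_cols(
                split$test[c("compound_id", "protein_id", "label")],
                dplyr::rename(pr, predicted = "label")),
              metrics = metrics)
  if (permuted_control) {
    y_perm <- with_seed(derive_seed(spec$seed, "permute"),
                        sample(feats$train$y))
    fit_perm <- train_network(feats$train$x, y_perm, spec)
    out$permuted_auroc <- auroc(feats$test$y,
                                predict(fit_perm, feats$test$x)$prob)
  }
  structure(out, class = "cpi_experiment")
}

#' @export
print.cpi_experiment <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("CPI experiment: %d train / %d test pairs\n",
              nrow(x$split$train), nrow(x$split$test)))
  cat(sprintf("  held-out ACC %.3f  AUROC %.3f  AUPR %.3f\n",
              m$acc, m$auroc, m$aupr))
  if (!is.null(x$permuted_auroc)) {
    cat(sprintf("  permuted-label control AUROC %.3f\n", x$permuted_auroc))
  }
  invisible(x)
}

#' @export
glance.cpi_experiment <- function(x, ...) {
  out <- x$metrics
  if (!is.null(x$permuted_auroc)) out$permuted_auroc <- x$permuted_auroc
  out
}

#' Typical embedding scale of a training set
#'
#' The median pairwise Euclidean distance among training-protein embeddings;
#' used to place the applicability threshold on the scale of the embedding
#' space at hand.
#'
#' @param embeddings Numeric matrix of embeddings.
#' @return Positive scalar.
#' @export
embedding_scale <- function(embeddings) {
  assert_that(nrow(embeddings) >= 2, "need at least 2 embeddings")
  stats::median(as.numeric(stats::dist(embeddings)))
}

#' Applicability analysis of a fitted experiment on external proteins
#'
#' Generates external proteins from the benchmark's latent model (a near
#' group inside the training domain, a far group outside it), embeds them
#' with the experiment's frozen word model, predicts their ground-truth
#' interactions with the benchmark compounds, and reports accuracy inside
#' and beyond the scaled critical distance `0.4 * s`, where `s` is the
#' training [embedding_scale()].
#'
#' @param experiment A [benchmark_experiment()] result.
#' @param bench The benchmark it was fitted on.
#' @param n_near,n_far External group sizes. Defaults 15 and 15.
#' @param n_compounds_eval Compounds sampled per external protein. Default
#'   300.
#' @param threshold_factor Critical value as a fraction of the embedding
#'   scale. Default 0.4.
#' @return List of class `cpi_applicability`: `domain` (per-protein nearest
#'   distances and verdicts), `by_protein` (per-protein accuracy), `acc_near`,
#'   `acc_far`, `scale`, `threshold` and `bins` (a [binned_performance()]
#'   report on the scaled distance).
#' @export
applicability_experiment <- function(experiment, bench,
                                     n_near = 15, n_far = 15,
                                     n_compounds_eval = 300,
                                     threshold_factor = 0.4) {
  ext <- generate_external_proteins(bench, n_near = n_near, n_far = n_far)
  wm <- experiment$features$word_model
  ext_emb <- embed_proteins(ext$proteins, wm)
  train_emb <- experiment$features$train_embeddings
  s <- embedding_scale(train_emb)
  threshold <- threshold_factor * s

  nd <- nearest_training_distance(ext_emb, train_emb)
  verdicts <- within_domain(nd$distance, threshold, protein_id = nd$protein_id)

  cmp_ids <- with_seed(derive_seed(bench$config$seed, "eval-compounds"), {
    sample(unique(experiment$split$train$compound_id),
           min(n_compounds_eval, length(unique(experiment$split$train$compound_id))))
  })
  truth <- ext$truth |>
    dplyr::filter(.data$compound_id %in% cmp_ids)
  comp_scores <- predict(experiment$features$pca,
                         stats::setNames(bench$compounds$fingerprint,
                                         bench$compounds$compound_id)[cmp_ids])
  built <- build_pair_matrix(truth[c("compound_id", "protein_id")],
                             comp_scores, ext_emb)
  pr <- predict(experiment$fit, built$x)
  y <- as.integer(truth$interacts)

  dist_map <- stats::setNames(nd$distance, nd$protein_id)
  d <- unname(dist_map[truth$protein_id])
  by_protein <- tibble::tibble(protein_id = truth$protein_id,
                               correct = pr$label == y,
                               distance = d) |>
    dplyr::group_by(.data$protein_id, .data$distance) |>
    dplyr::summarise(n = dplyr::n(), acc = mean(.data$correct), .groups = "drop")

  near_sel <- d <= threshold
  bins <- binned_performance(y, pr$prob, d / s,
                             edges = c(0, threshold_factor, 0.67, 1, 2, 3, 4, 10))
  structure(
    list(domain = verdicts, by_protein = by_protein,
         acc_near = mean(pr$label[near_sel] == y[near_sel]),
         acc_far = mean(pr$label[!near_sel] == y[!near_sel]),
         n_near_pairs = sum(near_sel), n_far_pairs = sum(!near_sel),
         scale = s, threshold = threshold, bins = bins),
    class = "cpi_applicability"
  )
}

#' @export
print.cpi_applicability <- function(x, ...) {
  cat(sprintf("Applicability analysis (scale %.3f, critical distance %.3f):\n",
              x$scale, x$threshold))
  cat(sprintf("  accuracy within domain:  %.3f (%d pairs)\n",
              x$acc_near, x$n_near_pairs))
  cat(sprintf("  accuracy outside domain: %.3f (%d pairs)\n",
              x$acc_far, x$n_far_pairs))
  invisible(x)
}
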