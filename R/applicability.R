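#' Distance or similarity between two protein embeddings
#'
#' @param a,b Numeric vectors of equal length.
#' @param metric `"euclidean"` (distance, >= 0) or `"cosine"` (similarity in
#'   `[-1, 1]`; errors on a zero vector).
#' @return A scalar.
#' @export
protein_distance <- function(a, b, metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  assert_that(length(a) == length(b), "embedding dimensions differ")
  if (metric == "euclidean") {
    sqrt(sum((a - b)^2))
  } else {
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    assert_that(na > 0 && nb > 0, "cosine similarity undefined for a zero vector")
    sum(a * b) / (na * nb)
  }
}

#' Global-alignment sequence identity
#'
#' Percentage of identical residue pairs over the global (Needleman-Wunsch)
#' alignment length, with a simple fixed scheme: match +1, mismatch 0,
#' gap -1.
#'
#' @param seqA,seqB Non-empty amino-acid strings.
#' @return Identity percentage in `[0, 100]`.
#' @export
sequence_identity <- function(seqA, seqB) {
  assert_that(is.character(seqA) && is.character(seqB) &&
                nchar(seqA) > 0 && nchar(seqB) > 0,
              "sequences must be non-empty strings")
  alpha <- unique(c(strsplit(paste0(seqA, seqB), "")[[1]], "X"))
  subm <- matrix(0, length(alpha), length(alpha), dimnames = list(alpha, alpha))
  diag(subm) <- 1
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::BString(seqA), Biostrings::BString(seqB),
    type = "global", substitutionMatrix = subm,
    gapOpening = 0, gapExtension = 1
  )
  Biostrings::pid(aln, type = "PID1")
}

#' Number of active compounds shared by two proteins
#'
#' Under the similarity-ensemble view, proteins with overlapping active
#' compound sets are functionally similar; this counts the overlap.
#'
#' @param protA,protB Protein ids.
#' @param positives Tibble of curated positive pairs (`compound_id`,
#'   `protein_id`).
#' @return Non-negative integer; 0 with a warning for an unknown protein.
#' @export
shared_active_count <- function(protA, protB, positives) {
  known <- unique(positives$protein_id)
  unknown <- setdiff(c(protA, protB), known)
  if (length(unknown) > 0) {
    rlang::warn(sprintf("protein(s) %s have no positives in the dataset",
                        paste(unknown, collapse = ", ")))
    if (!(protA %in% known) || !(protB %in% known)) return(0L)
  }
  actives <- function(p) unique(positives$compound_id[positives$protein_id == p])
  length(intersect(actives(protA), actives(protB)))
}

# assign values to half-open bins [lo, hi), last bin closed
bin_assign <- function(x, edges) {
  assert_that(length(edges) >= 2 && !is.unsorted(edges, strictly = TRUE),
              "bin edges must be strictly increasing")
  idx <- findInterval(x, edges, rightmost.closed = TRUE)
  idx[idx == 0 | idx == length(edges)] <- NA_integer_
  idx
}

bin_labels <- function(edges) {
  n <- length(edges) - 1
  close <- c(rep(")", n - 1), "]")
  sprintf("[%g, %g%s", edges[-length(edges)], edges[-1], close)
}

#' Relate protein-pair similarity to shared active compounds
#'
#' Bins every unordered protein pair by a similarity metric computed on
#' embeddings and summarizes the distribution of their shared-active-compound
#' counts per bin (used to validate that embedding distance tracks the
#' similarity of active compound sets).
#'
#' @param embeddings Numeric matrix of protein embeddings (rows named by
#'   protein id).
#' @param positives Tibble of positive pairs.
#' @param metric `"euclidean"` or `"cosine"`.
#' @param edges Bin edges on the metric.
#' @return Tibble: one row per bin with pair count and median/quartiles of
#'   shared counts.
#' @export
similarity_vs_shared_report <- function(embeddings, positives,
                                        metric = "euclidean",
                                        edges = c(0, 0.4, 0.67, 1, 2, 3, 4, 10)) {
  assert_that(nrow(embeddings) >= 2, "need at least 2 proteins")
  ids <- rownames(embeddings)
  combos <- utils::combn(seq_along(ids), 2)
  sims <- apply(combos, 2, function(ij) {
    protein_distance(embeddings[ij[1], ], embeddings[ij[2], ], metric)
  })
  actives <- split(positives$compound_id, positives$protein_id)
  shared <- apply(combos, 2, function(ij) {
    a <- actives[[ids[ij[1]]]]
    b <- actives[[ids[ij[2]]]]
    if (is.null(a) || is.null(b)) 0L else length(intersect(unique(a), unique(b)))
  })
  bins <- bin_assign(sims, edges)
  labs <- bin_labels(edges)
  purrr::map(seq_along(labs), function(k) {
    sh <- shared[!is.na(bins) & bins == k]
    tibble::tibble(
      bin = labs[k], lo = edges[k], hi = edges[k + 1],
      n_pairs = length(sh),
      shared_median = if (length(sh)) stats::median(sh) else NA_real_,
      shared_q1 = if (length(sh)) unname(stats::quantile(sh, 0.25)) else NA_real_,
      shared_q3 = if (length(sh)) unname(stats::quantile(sh, 0.75)) else NA_real_,
      shared_max = if (length(sh)) max(sh) else NA_real_
    )
  }) |> purrr::list_rbind()
}

#' Nearest training-protein distance
#'
#' Minimum Euclidean distance from each test protein's embedding to the
#' training protein embeddings, the similarity measure underpinning the
#' applicability domain.
#'
#' @param test_embeddings,train_embeddings Numeric matrices with protein ids
#'   as row names.
#' @return Tibble: `protein_id`, `nearest_id`, `distance`.
#' @export
nearest_training_distance <- function(test_embeddings, train_embeddings) {
  assert_that(nrow(train_embeddings) >= 1, "training set is empty")
  if (is.null(dim(test_embeddings))) {
    test_embeddings <- matrix(test_embeddings, nrow = 1)
  }
  # squared distances via the expansion |a-b|^2 = |a|^2 + |b|^2 - 2ab
  cross <- test_embeddings %*% t(train_embeddings)
  d2 <- outer(rowSums(test_embeddings^2), rowSums(train_embeddings^2), "+") - 2 * cross
  d2[d2 < 1e-12] <- 0 # clamp the expansion's floating-point residue
  j <- apply(d2, 1, which.min)
  tibble::tibble(
    protein_id = rownames(test_embeddings) %||% as.character(seq_len(nrow(d2))),
    nearest_id = rownames(train_embeddings)[j],
    distance = sqrt(d2[cbind(seq_len(nrow(d2)), j)])
  )
}

#' Applicability-domain verdict
#'
#' A protein is inside the model's applicability domain when its Euclidean
#' distance to the nearest training protein is at most the critical value
#' (default 0.4, inclusive).
#'
#' @param distance Non-negative nearest-training distances.
#' @param threshold Critical distance. Default 0.4.
#' @param protein_id Optional ids carried through.
#' @return Tibble: `protein_id` (if given), `distance`, `threshold`,
#'   `within_domain`.
#' @export
within_domain <- function(distance, threshold = 0.4, protein_id = NULL) {
  assert_that(all(distance >= 0), "distances must be non-negative")
  out <- tibble::tibble(distance = distance, threshold = threshold,
                        within_domain = distance <= threshold)
  if (!is.null(protein_id)) {
    out <- dplyr::bind_cols(tibble::tibble(protein_id = protein_id), out)
  }
  out
}

#' Performance binned by distance to the training set
#'
#' Splits predictions into half-open distance bins `[lo, hi)` (last bin
#' closed) and reports per-bin accuracy, AUROC where both classes are
#' present, and true/false prediction proportions.
#'
#' @param labels Binary true labels.
#' @param scores Predicted probabilities.
#' @param distances Nearest-training distances, aligned with `labels`.
#' @param edges Bin edges.
#' @param cutoff Probability cutoff. Default 0.5.
#' @return Tibble of class `cpi_bin_report`: one row per bin (`bin`, `lo`,
#'   `hi`, `n`, `acc`, `auroc`, `prop_true`, `prop_false`).
#' @export
binned_performance <- function(labels, scores, distances,
                               edges = c(0, 0.4, 0.67, 1, 2, 3, 4, 10),
                               cutoff = 0.5) {
  assert_that(length(labels) == length(scores) &&
                length(labels) == length(distances),
              "labels, scores and distances must be aligned")
  y <- as.integer(labels)
  bins <- bin_assign(distances, edges)
  if (anyNA(bins)) {
    rlang::warn(sprintf("%d pair(s) fall outside the bin edges and are dropped",
                        sum(is.na(bins))))
  }
  labs <- bin_labels(edges)
  out <- purrr::map(seq_along(labs), function(k) {
    sel <- !is.na(bins) & bins == k
    n <- sum(sel)
    if (n == 0) {
      return(tibble::tibble(bin = labs[k], lo = edges[k], hi = edges[k + 1],
                            n = 0L, acc = NA_real_, auroc = NA_real_,
                            prop_true = NA_real_, prop_false = NA_real_))
    }
    pred <- as.integer(scores[sel] >= cutoff)
    acc <- mean(pred == y[sel])
    au <- if (length(unique(y[sel])) == 2L) auroc(y[sel], scores[sel]) else NA_real_
    tibble::tibble(bin = labs[k], lo = edges[k], hi = edges[k + 1],
                   n = n, acc = acc, auroc = au,
                   prop_true = acc, prop_false = 1 - acc)
  }) |> purrr::list_rbind()
  class(out) <- c("cpi_bin_report", class(out))
  out
}

#' Plot a binned-performance report
#'
#' @param object A [binned_performance()] report.
#' @param ... Unused.
#' @return A ggplot: accuracy (and AUROC where defined) per distance bin.
#' @export
autoplot.cpi_bin_report <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::filter(object, .data$n > 0),
    cols = c("acc", "auroc"),
    names_to = "metric", values_to = "value"
  )
  df <- dplyr::filter(df, !is.na(.data$value))
  ggplot(df, aes(x = .data$bin, y = .data$value, fill = .data$metric)) +
    geom_col(position = "dodge") +
    labs(x = "Euclidean distance to nearest training protein",
         y = "Metric value", fill = NULL,
         title = "Performance by applicability-domain distance") +
    ylim(0, 1) +
    theme_minimal()
}
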