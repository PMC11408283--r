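# Independent brute-force oracles and small fixture builders used across the
# test files. These deliberately use naive scalar loops so they share no code
# path with the package implementations they check.

# O(n^2) pairwise-counting AUROC with half credit for ties
oracle_auroc <- function(labels, scores) {
  pos <- which(labels == 1)
  neg <- which(labels == 0)
  total <- 0
  for (i in pos) {
    for (j in neg) {
      if (scores[i] > scores[j]) total <- total + 1
      else if (scores[i] == scores[j]) total <- total + 0.5
    }
  }
  total / (length(pos) * length(neg))
}

# step-curve AUPR by explicit threshold enumeration with per-threshold
# confusion recomputation
oracle_aupr <- function(labels, scores) {
  thresholds <- sort(unique(scores), decreasing = TRUE)
  area <- 0
  prev_recall <- 0
  npos <- sum(labels == 1)
  for (t in thresholds) {
    tp <- 0; fp <- 0
    for (i in seq_along(scores)) {
      if (scores[i] >= t) {
        if (labels[i] == 1) tp <- tp + 1 else fp <- fp + 1
      }
    }
    precision <- tp / (tp + fp)
    recall <- tp / npos
    area <- area + precision * (recall - prev_recall)
    prev_recall <- recall
  }
  area
}

# definitional set-based Tanimoto
oracle_tanimoto <- function(a, b) {
  a <- unique(a); b <- unique(b)
  if (length(a) == 0 && length(b) == 0) return(0)
  length(intersect(a, b)) / length(union(a, b))
}

# scalar metrics by direct arithmetic
oracle_scalar_metrics <- function(tp, tn, fp, fn) {
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  list(acc = div(tp + tn, tp + tn + fp + fn),
       sen = div(tp, tp + fn),
       spe = div(tn, fp + tn),
       fpr = div(fp, fp + tn),
       precision = div(tp, tp + fp))
}

# exhaustive greedy ligand grouping oracle: visit compounds by descending
# count (ties by id), assign to the first retained leader with similarity
# above the cutoff, else retain
oracle_dedup_ids <- function(ids, counts, fps, cutoff) {
  ord <- order(-counts, ids)
  leaders <- integer(0)
  for (i in ord) {
    similar <- FALSE
    for (l in leaders) {
      if (oracle_tanimoto(fps[[i]], fps[[l]]) > cutoff) similar <- TRUE
    }
    if (!similar) leaders <- c(leaders, i)
  }
  sort(ids[leaders])
}

# random fingerprint as a sorted set of on-bit indices
random_fp <- function(nbits = 64, n_on = 12) {
  sort(sample.int(nbits, n_on))
}

# tiny curation input: records + compounds tables around the given pairs
make_records <- function(...) {
  rows <- list(...)
  purrr::map(rows, function(r) {
    tibble::tibble(
      compound_id = r$c, protein_id = r$p,
      assay_type = r$assay %||% "IC50",
      value = r$value %||% NA_real_,
      unit = r$unit %||% (if (is.null(r$value)) NA_character_ else "uM"),
      label = r$label %||% NA_character_,
      source = r$source %||% "dbA"
    )
  }) |> purrr::list_rbind()
}

`%||%` <- function(x, y) if (is.null(x)) y else x

golden_path <- function(file) {
  system.file("extdata", "golden", file, package = "cpipred")
}
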