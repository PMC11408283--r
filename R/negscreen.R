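#' Built-in compound descriptors
#'
#' A reproducible, license-free descriptor set for the correlation-space
#' screen: fingerprint bits folded into coarse count buckets plus simple
#' physicochemical proxies (molecular weight, on-bit count). Externally
#' computed descriptor tables with the same shape (entity id + numeric
#' columns) can be supplied anywhere these are accepted.
#'
#' @param compounds Tibble with `compound_id`, `mol_weight_Da` and a
#'   `fingerprint` list-column of on-bit indices.
#' @param n_buckets Number of fold buckets. Default 64.
#' @param nbits Fingerprint length. Default 2048.
#' @return Tibble: `compound_id` plus numeric descriptor columns.
#' @export
compound_descriptors <- function(compounds, n_buckets = 64, nbits = 2048) {
  assert_that(all(c("compound_id", "fingerprint") %in% names(compounds)),
              "`compounds` needs compound_id and fingerprint columns")
  width <- ceiling(nbits / n_buckets)
  buckets <- t(vapply(compounds$fingerprint, function(fp) {
    tabulate((fp - 1L) %/% width + 1L, nbins = n_buckets)
  }, numeric(n_buckets)))
  colnames(buckets) <- paste0("fpb", seq_len(n_buckets))
  mw <- if ("mol_weight_Da" %in% names(compounds)) compounds$mol_weight_Da else 0
  dplyr::bind_cols(
    tibble::tibble(compound_id = compounds$compound_id),
    tibble::as_tibble(buckets),
    tibble::tibble(mol_weight = mw, n_bits_on = lengths(compounds$fingerprint))
  )
}

.aa20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

#' Built-in protein descriptors
#'
#' Amino-acid composition over the 20 standard residues, a dipeptide
#' composition subset over a fixed reduced alphabet, and sequence length.
#'
#' @param proteins Tibble with `protein_id` and `sequence`.
#' @param dipeptides Include the dipeptide-composition block. Default TRUE.
#' @return Tibble: `protein_id` plus numeric descriptor columns.
#' @export
protein_descriptors <- function(proteins, dipeptides = TRUE) {
  assert_that(all(c("protein_id", "sequence") %in% names(proteins)),
              "`proteins` needs protein_id and sequence columns")
  comp <- t(vapply(proteins$sequence, function(s) {
    ch <- strsplit(s, "")[[1]]
    tabulate(factor(ch, levels = .aa20), nbins = 20) / length(ch)
  }, numeric(20)))
  colnames(comp) <- paste0("aac_", .aa20)
  out <- dplyr::bind_cols(
    tibble::tibble(protein_id = proteins$protein_id),
    tibble::as_tibble(comp)
  )
  if (dipeptides) {
    red <- c("A", "L", "G", "V", "E", "K", "S", "T") # reduced alphabet subset
    dipep <- as.vector(outer(red, red, paste0))
    dp <- t(vapply(proteins$sequence, function(s) {
      n <- nchar(s)
      if (n < 2) return(numeric(length(dipep)))
      pairs <- paste0(substring(s, 1:(n - 1), 1:(n - 1)),
                      substring(s, 2:n, 2:n))
      tabulate(factor(pairs, levels = dipep), nbins = length(dipep)) / (n - 1)
    }, numeric(length(dipep))))
    colnames(dp) <- paste0("dpc_", dipep)
    out <- dplyr::bind_cols(out, tibble::as_tibble(dp))
  }
  dplyr::bind_cols(out, tibble::tibble(seq_length = nchar(proteins$sequence)))
}

# split a descriptor tibble into id vector + numeric matrix
desc_matrix <- function(table) {
  id_col <- names(table)[1]
  m <- as.matrix(table[, -1, drop = FALSE])
  assert_that(is.numeric(m), "descriptor columns must be numeric")
  assert_that(!anyNA(m), "descriptor table contains missing values")
  rownames(m) <- table[[id_col]]
  m
}

#' Reduce a descriptor table by PCA
#'
#' @param table Descriptor tibble (entity id first, numeric columns after).
#' @param retain Either an integer component count, or a fraction in (0, 1)
#'   interpreted as the cumulative explained-variance target.
#' @return Tibble of principal-component scores with the same id column, plus
#'   a `"prop_variance"` attribute with the per-component variance fractions.
#' @export
reduce_descriptors <- function(table, retain = 0.95) {
  m <- desc_matrix(table)
  assert_that(nrow(m) >= 2 && ncol(m) >= 2,
              "need at least 2 entities and 2 descriptors")
  p <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  v <- p$sdev^2
  prop <- v / sum(v)
  rank <- sum(p$sdev > 1e-10)
  k <- if (retain < 1) {
    which(cumsum(prop) >= retain)[1]
  } else {
    as.integer(retain)
  }
  if (k > rank) {
    rlang::warn(sprintf("requested %d components exceeds rank %d; truncating", k, rank))
    k <- rank
  }
  scores <- p$x[, seq_len(k), drop = FALSE]
  out <- dplyr::bind_cols(table[, 1, drop = FALSE], tibble::as_tibble(scores))
  attr(out, "prop_variance") <- prop
  out
}

#' Fit the compound-target correlation space
#'
#' Canonical correlation analysis between the descriptor vectors of the
#' compounds and proteins of known positive pairs: paired linear projections
#' maximizing per-component correlation. Descriptors are standardized and the
#' covariance blocks ridge-regularized for stability on collinear input.
#'
#' @param positive_pairs Tibble with `compound_id`, `protein_id` (known
#'   interactions).
#' @param compound_desc,protein_desc Descriptor tibbles (id + numeric
#'   columns) covering at least the paired entities.
#' @param n_components Number of canonical components; default
#'   `min(5, rank)`.
#' @param ridge Ridge added to the covariance diagonals. Default 1e-6.
#' @return Object of class `cpi_cca`: projection weights (`wx`, `wy`),
#'   standardization statistics, and per-component `correlations`
#'   (non-increasing).
#' @export
fit_correlation_space <- function(positive_pairs, compound_desc, protein_desc,
                                  n_components = 5, ridge = 1e-6) {
  cm <- desc_matrix(compound_desc)
  pm <- desc_matrix(protein_desc)
  missing_c <- setdiff(positive_pairs$compound_id, rownames(cm))
  missing_p <- setdiff(positive_pairs$protein_id, rownames(pm))
  assert_that(length(missing_c) == 0 && length(missing_p) == 0,
              "descriptor rows missing for some paired entities")

  x <- cm[positive_pairs$compound_id, , drop = FALSE]
  y <- pm[positive_pairs$protein_id, , drop = FALSE]
  n <- nrow(x)
  assert_that(n >= 3, "need at least 3 positive pairs to fit the space")

  std <- function(m) {
    mu <- colMeans(m)
    sg <- apply(m, 2, stats::sd)
    sg[sg < 1e-12] <- 1
    list(mu = mu, sg = sg, z = sweep(sweep(m, 2, mu), 2, sg, "/"))
  }
  sx <- std(x); sy <- std(y)

  cxx <- stats::cov(sx$z) + diag(ridge, ncol(sx$z))
  cyy <- stats::cov(sy$z) + diag(ridge, ncol(sy$z))
  cxy <- stats::cov(sx$z, sy$z)

  # whitened cross-covariance SVD
  inv_sqrt <- function(s) {
    e <- eigen(s, symmetric = TRUE)
    vals <- pmax(e$values, ridge)
    e$vectors %*% diag(1 / sqrt(vals), length(vals)) %*% t(e$vectors)
  }
  kx <- inv_sqrt(cxx)
  ky <- inv_sqrt(cyy)
  sv <- svd(kx %*% cxy %*% ky)
  k <- min(n_components, length(sv$d), n - 1L)
  wx <- kx %*% sv$u[, seq_len(k), drop = FALSE]
  wy <- ky %*% sv$v[, seq_len(k), drop = FALSE]

  structure(
    list(wx = wx, wy = wy,
         x_center = sx$mu, x_scale = sx$sg,
         y_center = sy$mu, y_scale = sy$sg,
         n_components = k,
         correlations = pmin(pmax(sv$d[seq_len(k)], 0), 1)),
    class = "cpi_cca"
  )
}

#' @export
print.cpi_cca <- function(x, ...) {
  cat(sprintf("Compound-target correlation space: %d components\n", x$n_components))
  cat("  canonical correlations:",
      paste(sprintf("%.3f", x$correlations), collapse = " "), "\n")
  invisible(x)
}

#' @export
tidy.cpi_cca <- function(x, ...) {
  tibble::tibble(component = seq_len(x$n_components),
                 correlation = x$correlations)
}

#' Project descriptor rows into the correlation space
#'
#' Targets and candidate proteins are both projected with the protein-side
#' weights, compounds with the compound-side weights, so distances are
#' measured in a common canonical coordinate system.
#'
#' @param space A fitted `cpi_cca`.
#' @param desc Descriptor tibble (id + numeric columns).
#' @param side `"protein"` or `"compound"`.
#' @return Numeric matrix of canonical coordinates, rows named by entity id.
#' @export
project_entities <- function(space, desc, side = c("protein", "compound")) {
  side <- match.arg(side)
  m <- desc_matrix(desc)
  if (side == "protein") {
    z <- sweep(sweep(m, 2, space$y_center), 2, space$y_scale, "/")
    out <- z %*% space$wy
  } else {
    z <- sweep(sweep(m, 2, space$x_center), 2, space$x_scale, "/")
    out <- z %*% space$wx
  }
  colnames(out) <- paste0("cc", seq_len(ncol(out)))
  out
}

#' Distance threshold of a compound's target space
#'
#' All known positive targets of a compound form its target space. The
#' threshold is the upper limit of the 95% confidence interval of the mean
#' pairwise Euclidean distance among the targets:
#' `mean + t(0.975, m-1) * sd / sqrt(m)` over the `m` target pairs. With a
#' single pair (two targets) the threshold is that distance itself.
#'
#' @param coords Numeric matrix of target coordinates in the correlation
#'   space (>= 2 rows).
#' @return Positive scalar threshold.
#' @export
target_space_threshold <- function(coords) {
  assert_that(is.matrix(coords) && nrow(coords) >= 2,
              "a target space needs at least 2 targets")
  d <- as.numeric(stats::dist(coords))
  m <- length(d)
  if (m == 1L) return(d)
  mean(d) + stats::qt(0.975, df = m - 1L) * stats::sd(d) / sqrt(m)
}

#' Confirm one candidate negative by correlation-space distance
#'
#' The candidate protein is projected into the correlation space; the pair is
#' a confirmed negative when its minimum Euclidean distance to the compound's
#' known targets exceeds the target-space threshold. The minimum (nearest
#' target) is the conservative choice against discarding true binders.
#'
#' @param protein_coord Numeric vector: candidate protein's canonical
#'   coordinates.
#' @param target_coords Matrix of the compound's target coordinates.
#' @param threshold Target-space distance threshold.
#' @return List with `confirmed` (logical) and `min_distance`.
#' @export
confirm_negative <- function(protein_coord, target_coords, threshold) {
  d2 <- colSums((t(target_coords) - protein_coord)^2)
  md <- sqrt(min(d2))
  list(confirmed = md > threshold, min_distance = md)
}

#' Screen candidate negative pairs in the correlation space (CTCS-IPM style)
#'
#' For every compound with at least two known positive targets, a target
#' space and its distance threshold are built; each candidate negative pair
#' of that compound is then retained only if the candidate protein lies
#' further than the threshold from every target. Compounds without a usable
#' target space pass through unscreened.
#'
#' @param candidate_pairs Tibble of candidate negatives (`compound_id`,
#'   `protein_id`).
#' @param positive_pairs Tibble of known positives used to build target
#'   spaces.
#' @param compound_desc,protein_desc Descriptor tibbles.
#' @param space Optional pre-fitted `cpi_cca`; fitted from
#'   `positive_pairs` when omitted.
#' @param n_components,ridge Passed to [fit_correlation_space()].
#' @return Tibble: the candidate pairs plus `min_distance`, `threshold` and
#'   `verdict` in `retained` (confirmed negative), `rejected` (too close to
#'   the target space) or `unscreened`.
#' @export
screen_negatives <- function(candidate_pairs, positive_pairs,
                             compound_desc, protein_desc,
                             space = NULL, n_components = 5, ridge = 1e-6) {
  out_cols <- function(tbl, verdict, md = NA_real_, thr = NA_real_) {
    dplyr::mutate(tbl, min_distance = md, threshold = thr, verdict = verdict)
  }
  if (nrow(candidate_pairs) == 0) {
    return(out_cols(candidate_pairs, character(0), numeric(0), numeric(0)))
  }
  if (is.null(space)) {
    space <- fit_correlation_space(positive_pairs, compound_desc, protein_desc,
                                   n_components = n_components, ridge = ridge)
  }
  prot_coords <- project_entities(space, protein_desc, "protein")

  targets_by_compound <- positive_pairs |>
    dplyr::filter(.data$protein_id %in% rownames(prot_coords)) |>
    dplyr::distinct(.data$compound_id, .data$protein_id) |>
    dplyr::group_by(.data$compound_id) |>
    dplyr::summarise(targets = list(.data$protein_id), .groups = "drop")
  tmap <- stats::setNames(targets_by_compound$targets,
                          targets_by_compound$compound_id)

  res <- purrr::pmap(candidate_pairs[c("compound_id", "protein_id")],
                     function(compound_id, protein_id) {
    tg <- tmap[[compound_id]]
    if (is.null(tg) || length(tg) < 2 || !(protein_id %in% rownames(prot_coords))) {
      return(tibble::tibble(min_distance = NA_real_, threshold = NA_real_,
                            verdict = "unscreened"))
    }
    tc <- prot_coords[tg, , drop = FALSE]
    thr <- target_space_threshold(tc)
    cn <- confirm_negative(prot_coords[protein_id, ], tc, thr)
    tibble::tibble(min_distance = cn$min_distance, threshold = thr,
                   verdict = if (cn$confirmed) "retained" else "rejected")
  }) |> purrr::list_rbind()

  dplyr::bind_cols(candidate_pairs, res)
}
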