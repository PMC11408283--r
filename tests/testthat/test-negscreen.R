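# small helper: descriptor tables that carry a 2-d latent plus noise columns
make_latent_descriptors <- function(ids, latents, prefix, noise_cols = 3,
                                    noise_sd = 0.05) {
  n <- nrow(latents)
  m <- cbind(latents + matrix(rnorm(n * ncol(latents), 0, noise_sd), n),
             matrix(rnorm(n * noise_cols), n))
  colnames(m) <- paste0(prefix, seq_len(ncol(m)))
  dplyr::bind_cols(tibble::tibble(id = ids), tibble::as_tibble(m)) |>
    rlang::set_names(c(if (prefix == "c") "compound_id" else "protein_id",
                       colnames(m)))
}

test_that("descriptor PCA reduction orders components and respects rank", {
  # 2-d data on a line: one component carries ~all variance
  line <- tibble::tibble(protein_id = sprintf("p%d", 1:10),
                         d1 = 1:10, d2 = 2 * (1:10))
  expect_warning(reduce_descriptors(line, retain = 2), "truncat")
  red <- suppressWarnings(reduce_descriptors(line, retain = 2))
  prop <- attr(red, "prop_variance")
  expect_gt(prop[1], 0.999)
  expect_equal(sum(prop), 1, tolerance = 1e-12)

  set.seed(1)
  tbl <- dplyr::bind_cols(tibble::tibble(compound_id = sprintf("c%d", 1:5)),
                          tibble::as_tibble(matrix(rnorm(20), 5, 4,
                                                   dimnames = list(NULL, paste0("d", 1:4)))))
  red4 <- reduce_descriptors(tbl, retain = 4)
  # identity request: reconstruction from all components is exact
  m <- as.matrix(tbl[, -1])
  p <- prcomp(m)
  rec <- p$x %*% t(p$rotation)
  expect_equal(sweep(rec, 2, -p$center), m, tolerance = 1e-10,
               ignore_attr = TRUE)
  # variance fractions sum to one and match the eigendecomposition oracle
  eig <- eigen(cov(m), symmetric = TRUE)$values
  expect_equal(attr(red4, "prop_variance"), eig / sum(eig), tolerance = 1e-10)
  expect_warning(reduce_descriptors(tbl, retain = 10), "truncat")
})

test_that("canonical correlation space maximizes paired correlation", {
  set.seed(2)
  d <- matrix(rnorm(40 * 4), 40, 4)
  cd <- dplyr::bind_cols(tibble::tibble(compound_id = sprintf("c%d", 1:40)),
                         tibble::as_tibble(matrix(d, 40, dimnames = list(NULL, paste0("x", 1:4)))))
  pd <- dplyr::bind_cols(tibble::tibble(protein_id = sprintf("p%d", 1:40)),
                         tibble::as_tibble(matrix(d, 40, dimnames = list(NULL, paste0("y", 1:4)))))
  pairs <- tibble::tibble(compound_id = cd$compound_id, protein_id = pd$protein_id)

  # identically paired descriptors: first canonical correlation ~ 1
  sp <- fit_correlation_space(pairs, cd, pd, n_components = 3)
  expect_gt(sp$correlations[1], 0.999)
  # correlations are non-increasing
  expect_true(all(diff(sp$correlations) <= 1e-8))

  # agreement with the established CCA on a well-conditioned problem
  set.seed(3)
  y2 <- d %*% matrix(rnorm(16), 4) + matrix(rnorm(160, 0, 0.5), 40)
  pd2 <- dplyr::bind_cols(tibble::tibble(protein_id = pd$protein_id),
                          tibble::as_tibble(matrix(y2, 40, dimnames = list(NULL, paste0("y", 1:4)))))
  sp2 <- fit_correlation_space(pairs, cd, pd2, n_components = 2, ridge = 1e-10)
  ref <- stats::cancor(scale(d), scale(y2))
  expect_equal(sp2$correlations, ref$cor[1:2], tolerance = 1e-4)

  # independent pairings: correlations stay low (permutation null)
  perm_cors <- replicate(20, {
    shuffled <- pairs
    shuffled$protein_id <- sample(shuffled$protein_id)
    fit_correlation_space(shuffled, cd, pd2, n_components = 1)$correlations[1]
  })
  expect_gt(sp2$correlations[1], max(perm_cors) * 0.9)
})

test_that("projection is invariant to descriptor rescaling", {
  set.seed(4)
  d <- matrix(rnorm(30 * 3), 30, 3)
  y <- d + matrix(rnorm(90, 0, 0.2), 30)
  cd <- dplyr::bind_cols(tibble::tibble(compound_id = sprintf("c%d", 1:30)),
                         tibble::as_tibble(matrix(d, 30, dimnames = list(NULL, paste0("x", 1:3)))))
  pd <- dplyr::bind_cols(tibble::tibble(protein_id = sprintf("p%d", 1:30)),
                         tibble::as_tibble(matrix(y, 30, dimnames = list(NULL, paste0("y", 1:3)))))
  pairs <- tibble::tibble(compound_id = cd$compound_id, protein_id = pd$protein_id)
  sp <- fit_correlation_space(pairs, cd, pd, n_components = 2)
  base <- project_entities(sp, pd, "protein")

  pd_scaled <- pd
  pd_scaled$y2 <- pd_scaled$y2 * 1000 # standardization absorbs column scaling
  sp_s <- fit_correlation_space(pairs, cd, pd_scaled, n_components = 2)
  scaled <- project_entities(sp_s, pd_scaled, "protein")
  # coordinates agree up to component sign
  for (k in 1:2) {
    expect_true(isTRUE(all.equal(base[, k], scaled[, k], tolerance = 1e-6)) ||
                  isTRUE(all.equal(base[, k], -scaled[, k], tolerance = 1e-6)))
  }
})

test_that("target-space thresholds are t-based CI upper limits of mean pair distance", {
  # two targets at distance 2: single pair, degenerate rule
  two <- matrix(c(0, 0, 2, 0), 2, byrow = TRUE)
  expect_equal(target_space_threshold(two), 2)

  # three collinear targets at 0, 1, 2: pairwise distances {1, 1, 2}
  three <- matrix(c(0, 0, 1, 0, 2, 0), 3, byrow = TRUE)
  dists <- c(1, 1, 2)
  want <- mean(dists) + qt(0.975, 2) * sd(dists) / sqrt(3)
  expect_equal(mean(dists), 4 / 3)
  expect_equal(target_space_threshold(three), want, tolerance = 1e-12)

  # the threshold never falls below the mean pairwise distance
  set.seed(5)
  for (i in 1:10) {
    coords <- matrix(rnorm(sample(2:6, 1) * 3), ncol = 3)
    expect_gte(target_space_threshold(coords),
               mean(as.numeric(dist(coords))) - 1e-12)
  }
  expect_error(target_space_threshold(matrix(0, 1, 2)), "at least 2")
})

test_that("negative confirmation compares nearest-target distance to the threshold", {
  targets <- matrix(c(0, 0, 1, 0), 2, byrow = TRUE)
  thr <- target_space_threshold(targets)
  # coincident with a known target: rejected from the negatives
  expect_false(confirm_negative(c(0, 0), targets, thr)$confirmed)
  # ten thresholds away from everything: confirmed
  far <- confirm_negative(c(0, 10 * thr + 1), targets, thr)
  expect_true(far$confirmed)
  expect_equal(far$min_distance, sqrt(0 + (10 * thr + 1)^2), tolerance = 1e-12)
})

test_that("screening partitions candidates and matches direct recomputation", {
  set.seed(6)
  n_comp <- 20; n_prot <- 15
  uc <- matrix(rnorm(n_comp * 2), n_comp, 2)
  up <- matrix(rnorm(n_prot * 2), n_prot, 2)
  cd <- make_latent_descriptors(sprintf("c%02d", 1:n_comp), uc, "c")
  pd <- make_latent_descriptors(sprintf("p%02d", 1:n_prot), up, "p")

  # positives: each of the first 12 compounds gets its 3 nearest proteins
  pos <- purrr::map(1:12, function(i) {
    d <- colSums((t(up) - uc[i, ])^2)
    tibble::tibble(compound_id = sprintf("c%02d", i),
                   protein_id = sprintf("p%02d", order(d)[1:3]))
  }) |> purrr::list_rbind()

  cand <- tidyr::expand_grid(compound_id = sprintf("c%02d", c(1:5, 15:20)),
                             protein_id = sprintf("p%02d", 1:n_prot)) |>
    dplyr::anti_join(pos, by = c("compound_id", "protein_id"))

  scr <- screen_negatives(cand, pos, cd, pd, n_components = 2)
  # partition: counts conserved, verdicts exhaustive
  expect_equal(nrow(scr), nrow(cand))
  expect_true(all(scr$verdict %in% c("retained", "rejected", "unscreened")))
  # compounds without >= 2 targets are exactly the unscreened ones
  no_space <- setdiff(unique(cand$compound_id), unique(pos$compound_id))
  expect_setequal(unique(scr$compound_id[scr$verdict == "unscreened"]), no_space)

  # oracle: recompute every distance and threshold from scratch
  sp <- fit_correlation_space(pos, cd, pd, n_components = 2)
  coords <- project_entities(sp, pd, "protein")
  for (i in which(scr$verdict != "unscreened")) {
    tg <- pos$protein_id[pos$compound_id == scr$compound_id[i]]
    tc <- coords[tg, , drop = FALSE]
    thr <- target_space_threshold(tc)
    md <- sqrt(min(colSums((t(tc) - coords[scr$protein_id[i], ])^2)))
    expect_equal(scr$min_distance[i], md, tolerance = 1e-10)
    expect_equal(scr$threshold[i], thr, tolerance = 1e-10)
    expect_equal(scr$verdict[i] == "retained", md > thr)
  }

  # empty candidate list: empty partition
  empty <- screen_negatives(cand[0, ], pos, cd, pd)
  expect_equal(nrow(empty), 0)
})

test_that("planted distant negatives are recalled by the screen", {
  set.seed(7)
  n_comp <- 12
  uc <- matrix(rnorm(n_comp * 2), n_comp, 2)
  # each compound has 4 targets tightly clustered at its own latent
  prot_lat <- purrr::map(seq_len(n_comp), function(i) {
    uc[i, ] + matrix(rnorm(8, 0, 0.1), 4, 2)
  })
  up <- do.call(rbind, prot_lat)
  pids <- sprintf("p%03d", seq_len(nrow(up)))
  pos <- tibble::tibble(
    compound_id = rep(sprintf("c%02d", 1:n_comp), each = 4),
    protein_id = pids
  )
  # planted true negatives: proteins far from every target cluster
  far_lat <- matrix(rnorm(20 * 2, 0, 1), 20, 2) + 8
  far_ids <- sprintf("f%03d", 1:20)
  cd <- make_latent_descriptors(sprintf("c%02d", 1:n_comp), uc, "c")
  pd <- make_latent_descriptors(c(pids, far_ids), rbind(up, far_lat), "p")

  cand <- tidyr::expand_grid(compound_id = sprintf("c%02d", 1:n_comp),
                             protein_id = far_ids)
  scr <- screen_negatives(cand, pos, cd, pd, n_components = 2)
  recall <- mean(scr$verdict == "retained")
  expect_gte(recall, 0.9)
})
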