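cfg_small <- generator_config(n_compounds = 60, n_proteins = 12, nbits = 256,
                              seed = 123)

test_that("compound generation is seeded, twin-planting controls Tanimoto", {
  cmp <- generate_compounds(cfg_small)
  cmp2 <- generate_compounds(cfg_small)
  expect_identical(cmp, cmp2)

  # twins exceed the redundancy cutoff by construction
  twins <- cmp[!is.na(cmp$twin_of), ]
  expect_gt(nrow(twins), 0)
  for (i in seq_len(nrow(twins))) {
    base_fp <- cmp$fingerprint[[match(twins$twin_of[i], cmp$compound_id)]]
    expect_gt(tanimoto(twins$fingerprint[[i]], base_fp), 0.8)
  }

  # with the rate at zero, no pair crosses the cutoff (exhaustive at this n)
  cfg0 <- generator_config(n_compounds = 50, n_proteins = 5, nbits = 256,
                           near_duplicate_rate = 0, seed = 5)
  cmp0 <- generate_compounds(cfg0)
  combs <- utils::combn(nrow(cmp0), 2)
  sims <- apply(combs, 2, function(ij) {
    tanimoto(cmp0$fingerprint[[ij[1]]], cmp0$fingerprint[[ij[2]]])
  })
  expect_lt(max(sims), 0.8)
})

test_that("protein generation respects length range and residue alphabet", {
  prot <- generate_proteins(cfg_small)
  lens <- nchar(prot$sequence)
  expect_true(all(lens >= cfg_small$protein_length_range[1]))
  expect_true(all(lens <= cfg_small$protein_length_range[2]))
  letters_used <- unique(strsplit(paste(prot$sequence, collapse = ""), "")[[1]])
  expect_true(all(letters_used %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]))
  expect_identical(prot, generate_proteins(cfg_small))
})

test_that("proteins with equal latents embed closer than random pairs", {
  cfg <- generator_config(n_compounds = 10, n_proteins = 30, nbits = 128,
                          seed = 42)
  lat <- matrix(rnorm(30 * cfg$latent_dim), 30, cfg$latent_dim)
  # 10 latents, each duplicated: pairs (1,2), (3,4), ... share v exactly
  lat[seq(2, 20, 2), ] <- lat[seq(1, 19, 2), ]
  prot <- generate_proteins(cfg, latents = lat)
  wm <- train_word_model(lapply(prot$sequence, tokenize_protein),
                         word_model_config(dim = 24, epochs = 5, seed = 1))
  emb <- embed_proteins(prot, wm)
  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  same_v <- purrr::map_dbl(seq(1, 19, 2),
                           function(i) cosine(emb[i, ], emb[i + 1, ]))
  set.seed(9)
  rand <- purrr::map_dbl(1:50, function(i) {
    ij <- sample(21:30, 2)
    cosine(emb[ij[1], ], emb[ij[2], ])
  })
  expect_gt(mean(same_v), mean(rand))
})

test_that("interaction truth follows the latent logistic model", {
  # temperature -> 0: labels deterministic from the sign of u . v
  cfg_det <- generator_config(n_compounds = 30, n_proteins = 8, nbits = 128,
                              interaction_temperature = 1e-9,
                              label_noise_rate = 0, seed = 3)
  cmp <- generate_compounds(cfg_det)
  prot <- generate_proteins(cfg_det)
  inter <- generate_interactions(cmp, prot, cfg_det)
  u <- do.call(rbind, cmp$latent)
  v <- do.call(rbind, prot$latent)
  uv <- as.numeric(u %*% t(v))
  expect_equal(inter$truth$interacts, uv > 0)

  # the empirical positive rate matches the analytic expectation: u . v is
  # symmetric around zero, so E[plogis(u.v / T)] = 1/2 exactly
  cfg_big <- generator_config(n_compounds = 150, n_proteins = 40, nbits = 64,
                              seed = 8)
  b <- generate_benchmark(cfg_big)
  expect_lt(abs(mean(b$truth$interacts) - 0.5), 0.05)

  # every multi-source pair carries at least two records
  dup_keys <- b$records |>
    dplyr::count(compound_id, protein_id) |>
    dplyr::filter(n >= 2)
  expect_gt(nrow(dup_keys), 0)
  expect_true(all(table(paste(b$records$compound_id, b$records$protein_id)) >= 1))
})

test_that("benchmark fixtures round-trip through the standard file formats", {
  dir <- withr::local_tempdir()
  cfg <- generator_config(n_compounds = 25, n_proteins = 5, nbits = 128,
                          seed = 21)
  paths <- make_benchmark_fixture(cfg, dir)
  bench <- paths$benchmark

  rec <- read_bioactivity(paths$records)
  expect_equal(nrow(rec), nrow(bench$records))
  expect_equal(rec$value, bench$records$value)

  cmp <- read_compounds(paths$compounds)
  expect_equal(cmp$compound_id, bench$compounds$compound_id)
  expect_identical(purrr::map(cmp$fingerprint, as.integer),
                   purrr::map(bench$compounds$fingerprint, as.integer))

  prot <- read_proteins(paths$proteins)
  expect_equal(prot$sequence, bench$proteins$sequence)

  # distinct seeds give distinct truth matrices
  cfg2 <- generator_config(n_compounds = 25, n_proteins = 5, nbits = 128,
                           seed = 22)
  b2 <- generate_benchmark(cfg2)
  expect_false(identical(b2$truth$interacts, bench$truth$interacts))
})

test_that("external proteins split into near and far families", {
  cfg <- generator_config(n_compounds = 20, n_proteins = 10, nbits = 128,
                          seed = 31)
  b <- generate_benchmark(cfg)
  ext <- generate_external_proteins(b, n_near = 4, n_far = 4)
  expect_equal(table(ext$proteins$group)[["near"]], 4)
  expect_equal(table(ext$proteins$group)[["far"]], 4)
  expect_equal(nrow(ext$truth), 8 * nrow(b$compounds))
  lens <- nchar(ext$proteins$sequence)
  expect_true(all(lens >= cfg$protein_length_range[1] &
                    lens <= cfg$protein_length_range[2]))
})
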