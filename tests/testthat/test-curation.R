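test_that("activity resolution follows threshold, min-value and any-active rules", {
  cfg <- curation_config()

  # single potent record
  r <- resolve_activity(make_records(list(c = "C1", p = "P1", value = 5)), cfg)
  expect_equal(r$label, "positive")
  expect_equal(r$representative_value_uM, 5)

  # boundary is inclusive at 10 uM
  r <- resolve_activity(make_records(list(c = "C1", p = "P1", value = 10)), cfg)
  expect_equal(r$label, "positive")

  # all-negative records: negative with the minimum as representative
  r <- resolve_activity(make_records(
    list(c = "C1", p = "P1", assay = "Ki", value = 15),
    list(c = "C1", p = "P1", assay = "Ki", value = 20)
  ), cfg)
  expect_equal(r$label, "negative")
  expect_equal(r$representative_value_uM, 15)

  # any-active dominates a weak potency
  r <- resolve_activity(make_records(
    list(c = "C1", p = "P1", value = 20),
    list(c = "C1", p = "P1", assay = "BINARY", label = "active", source = "dbB")
  ), cfg)
  expect_equal(r$label, "positive")
  expect_true(r$conflict)

  # representative is the minimum over all orderings of the value set
  vals <- c(8, 3, 20)
  for (perm in list(c(1, 2, 3), c(3, 2, 1), c(2, 3, 1))) {
    recs <- purrr::map(vals[perm],
                       function(v) list(c = "C1", p = "P1", value = v))
    r <- resolve_activity(do.call(make_records, recs), cfg)
    expect_equal(r$label, "positive")
    expect_equal(r$representative_value_uM, 3)
  }

  # no interpretable record
  r <- resolve_activity(make_records(
    list(c = "C1", p = "P1", value = NULL)), cfg)
  expect_null(r)
})

test_that("adding a positive record never flips a pair to negative", {
  cfg <- curation_config()
  set.seed(42)
  for (i in 1:20) {
    n <- sample(1:4, 1)
    base <- purrr::map(seq_len(n), function(j) {
      list(c = "C1", p = "P1", value = runif(1, 0.1, 100))
    })
    r0 <- resolve_activity(do.call(make_records, base), cfg)
    extra <- c(base, list(list(c = "C1", p = "P1", value = runif(1, 0.1, 10))))
    r1 <- resolve_activity(do.call(make_records, extra), cfg)
    expect_equal(r1$label, "positive")
    if (r0$label == "positive") expect_equal(r1$label, "positive")
  }
})

test_that("unit normalization converts to micromolar and rejects unknown units", {
  expect_equal(normalize_potency(c(5, 5000, 0.005), c("uM", "nM", "mM")),
               c(5, 5, 5))
  expect_warning(v <- normalize_potency(c(1, 2), c("uM", "furlongs")),
                 "unrecognized")
  expect_equal(v, c(1, NA))
})

test_that("molecular weight filter keeps the inclusive 100-1000 Da window", {
  cmp <- tibble::tibble(
    compound_id = c("a", "b", "c", "d", "e"),
    mol_weight_Da = c(99.9, 100, 1000, 1500, NA)
  )
  expect_warning(kept <- filter_by_weight(cmp), "without molecular weight")
  expect_setequal(kept$compound_id, c("b", "c"))
})

test_that("tanimoto matches its set definition", {
  expect_equal(tanimoto(c(1, 2, 3), c(2, 3, 4)), 0.5)
  expect_equal(tanimoto(c(5, 9), c(5, 9)), 1)
  expect_equal(tanimoto(c(1, 2), c(3, 4)), 0)
  expect_equal(tanimoto(integer(0), integer(0)), 0)
  # logical-vector form requires equal lengths
  expect_error(tanimoto(c(TRUE, FALSE), c(TRUE, FALSE, TRUE)), "equal bit length")

  set.seed(7)
  for (i in 1:50) {
    a <- random_fp(); b <- random_fp()
    expect_equal(tanimoto(a, b), oracle_tanimoto(a, b))
  }
})

test_that("ligand deduplication keeps the most-connected compound per similar group", {
  cfg <- curation_config()
  # three mutually similar compounds: keep only the count-5 one
  base <- 1:10
  grp <- tibble::tibble(
    compound_id = c("x", "y", "z"),
    interaction_count = c(5, 3, 1),
    fingerprint = list(base, c(base[-1], 11L), c(base[-2], 12L))
  )
  stopifnot(tanimoto(grp$fingerprint[[1]], grp$fingerprint[[2]]) > 0.8)
  kept <- deduplicate_ligand_bias(grp, cfg, nbits = 64)
  expect_equal(kept$compound_id, "x")

  # dissimilar pair: both kept
  grp2 <- tibble::tibble(
    compound_id = c("x", "y"), interaction_count = c(2, 1),
    fingerprint = list(c(1L, 2L, 3L, 4L), c(3L, 4L, 5L, 6L))
  )
  expect_equal(nrow(deduplicate_ligand_bias(grp2, cfg, nbits = 64)), 2)
})

test_that("deduplication equals the brute-force greedy oracle and is idempotent", {
  cfg <- curation_config()
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(4:10, 1)
    grp <- tibble::tibble(
      compound_id = sprintf("c%02d", seq_len(n)),
      interaction_count = sample(1:5, n, replace = TRUE),
      fingerprint = purrr::map(seq_len(n), ~ random_fp(nbits = 24, n_on = 10))
    )
    kept <- deduplicate_ligand_bias(grp, cfg, nbits = 24)
    expect_equal(sort(kept$compound_id),
                 oracle_dedup_ids(grp$compound_id, grp$interaction_count,
                                  grp$fingerprint, cfg$tanimoto_cutoff))
    twice <- deduplicate_ligand_bias(kept, cfg, nbits = 24)
    expect_equal(sort(twice$compound_id), sort(kept$compound_id))
  }
})

test_that("negative capping respects the cap and mutual dissimilarity", {
  cfg <- curation_config(negatives_cap_per_protein = 5)
  set.seed(3)
  n <- 30
  grp <- tibble::tibble(
    compound_id = sprintf("c%02d", seq_len(n)),
    interaction_count = sample(1:50, n),
    fingerprint = purrr::map(seq_len(n), ~ random_fp(nbits = 40, n_on = 15))
  )
  kept <- cap_negatives_per_protein(grp, cfg, nbits = 40)
  expect_lte(nrow(kept), 5)
  # every retained pair of survivors is below the cutoff (exhaustive check)
  if (nrow(kept) > 1) {
    combs <- utils::combn(nrow(kept), 2)
    for (k in seq_len(ncol(combs))) {
      expect_lt(tanimoto(kept$fingerprint[[combs[1, k]]],
                         kept$fingerprint[[combs[2, k]]]),
                cfg$tanimoto_cutoff)
    }
  }

  # a candidate similar to an accepted survivor is skipped even under the cap
  grp3 <- tibble::tibble(
    compound_id = c("lead", "twin", "other"),
    interaction_count = c(10, 5, 1),
    fingerprint = list(1:10, c(2:10, 11L), 30:35)
  )
  stopifnot(tanimoto(grp3$fingerprint[[1]], grp3$fingerprint[[2]]) > 0.8)
  kept3 <- cap_negatives_per_protein(grp3, curation_config(), nbits = 64)
  expect_setequal(kept3$compound_id, c("lead", "other"))

  # under the cap, everything dissimilar is retained
  expect_equal(nrow(cap_negatives_per_protein(grp3[3, ], curation_config(),
                                              nbits = 64)), 1)
})

test_that("overlap statistics are symmetric, bounded and relative to the smaller set", {
  expect_equal(overlap_percentage(825533, 905350, 558453), 67.65)
  expect_equal(overlap_percentage(12941, 825533, 3158), 24.40)
  expect_true(is.na(overlap_percentage(0, 10, 0)))

  a <- sprintf("k%d", 1:100)
  b <- sprintf("k%d", 51:130)
  st <- dataset_overlap_stats(list(A = a, B = b))
  ov <- st[st$dataset_a == "A" & st$dataset_b == "B", ]
  expect_equal(ov$overlap, 50)
  expect_equal(ov$pct_of_smaller, 100 * 50 / 80)
  # symmetry in the inputs
  st2 <- dataset_overlap_stats(list(B = b, A = a))
  ov2 <- st2[st2$dataset_a == "B" & st2$dataset_b == "A", ]
  expect_equal(ov2$pct_of_smaller, ov$pct_of_smaller)
  # identical sets overlap fully
  st3 <- dataset_overlap_stats(list(A = a, A2 = a))
  expect_equal(st3$pct_of_smaller[st3$dataset_a == "A" & st3$dataset_b == "A2"], 100)
  # bounds
  expect_true(all(st$pct_of_smaller >= 0 & st$pct_of_smaller <= 100))
})

test_that("train/test split is disjoint, exhaustive, rounded and seeded", {
  pairs <- tibble::tibble(compound_id = sprintf("c%d", 1:10),
                          protein_id = "p", label = "positive")
  cfg <- curation_config(seed = 5)
  sp <- split_dataset(pairs, cfg)
  expect_equal(nrow(sp$train), 8)
  expect_equal(nrow(sp$test), 2)
  expect_equal(nrow(dplyr::intersect(sp$train, sp$test)), 0)
  expect_equal(nrow(dplyr::bind_rows(sp$train, sp$test)), 10)

  sp2 <- split_dataset(pairs, cfg)
  expect_identical(sp, sp2)

  # round-half-up on the train side at the benchmark's published size
  expect_equal(floor(0.8 * 1014627 + 0.5), 811702)
  expect_error(split_dataset(pairs[1:3, ], cfg), "at least 5")
})

test_that("curation keeps unique pair keys and consistent label counts", {
  set.seed(9)
  b <- generate_benchmark(generator_config(n_compounds = 40, n_proteins = 6,
                                           nbits = 128, seed = 9))
  cur <- suppressMessages(curate_dataset(b$records, b$compounds,
                                         curation_config(), nbits = 128))
  keys <- paste(cur$pairs$compound_id, cur$pairs$protein_id)
  expect_equal(anyDuplicated(keys), 0)
  expect_equal(sum(cur$pairs$label == "positive") +
                 sum(cur$pairs$label == "negative"), nrow(cur$pairs))
  expect_s3_class(glance(cur), "tbl_df")
})
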