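test_that("protein tokenization yields non-overlapping 3-mers in one frame", {
  expect_equal(tokenize_protein("MKVLAA"), c("MKV", "LAA"))
  expect_equal(tokenize_protein("MKVLAAG"), c("MKV", "LAA")) # trailing G dropped
  expect_error(tokenize_protein("MK"), "shorter")

  set.seed(1)
  for (len in 3:30) {
    s <- paste(sample(LETTERS[1:20], len, replace = TRUE), collapse = "")
    expect_length(tokenize_protein(s), len %/% 3)
  }
})

test_that("Morgan fingerprints are canonical, structure-sensitive and non-empty", {
  fps <- morgan_fingerprint(c("c1ccccc1", "C1=CC=CC=C1", "C", "CCCCCCCCCC"))
  expect_identical(fps[[1]], fps[[2]]) # two spellings of benzene
  expect_lt(tanimoto(fps[[3]], fps[[4]]), 1) # methane vs decane
  expect_gt(length(fps[[4]]), 0)
  expect_true(all(purrr::map_int(fps, max) <= 2048))
  expect_error(morgan_fingerprint(c("CCO", "not_a_smiles(((")), "record 2")
})

test_that("compound PCA is an ordered eigendecomposition of the bit matrix", {
  # one repeated fingerprint: no variance, transforms to ~0
  rep_fp <- replicate(5, c(1L, 4L, 9L), simplify = FALSE)
  p0 <- fit_compound_pca(rep_fp, n = 2, nbits = 16)
  sc0 <- predict(p0, rep_fp)
  expect_lt(max(abs(sc0)), 1e-8)
  expect_true(all(p0$sdev < 1e-10))
  # requesting more components than the data can support warns and truncates
  expect_warning(pt <- fit_compound_pca(rep_fp, n = 10, nbits = 16), "truncat")
  expect_lte(pt$n_components, 4)

  set.seed(2)
  fps <- purrr::map(1:10, ~ sort(sample.int(16, 6)))
  pca <- fit_compound_pca(fps, n = 3, nbits = 16)
  expect_equal(pca$n_components, 3)
  v <- pca$sdev^2
  expect_true(all(diff(v) <= 1e-12))

  # scores match a direct eigendecomposition oracle (up to component sign)
  x <- matrix(0, 10, 16)
  for (i in 1:10) x[i, fps[[i]]] <- 1
  xc <- scale(x, center = TRUE, scale = FALSE)
  eig <- eigen(crossprod(xc) / (nrow(x) - 1), symmetric = TRUE)
  want <- xc %*% eig$vectors[, 1:3]
  got <- predict(pca, fps)
  for (k in 1:3) {
    expect_true(isTRUE(all.equal(got[, k], want[, k], tolerance = 1e-8)) ||
                  isTRUE(all.equal(got[, k], -want[, k], tolerance = 1e-8)))
  }

  # the training mean transforms to the zero vector
  mean_row <- matrix(colMeans(x), 1)
  expect_lt(max(abs(predict(pca, mean_row))), 1e-10)
})

test_that("CBOW training yields finite vectors and context-driven similarity", {
  # two disjoint topics: words of the same topic share contexts, words of
  # different topics never co-occur
  set.seed(3)
  topic1 <- c("AAA", "CCC", "FFF", "GGG", "HHH")
  topic2 <- c("DDD", "EEE", "III", "KKK", "LLL")
  corpus <- purrr::map(1:60, function(i) {
    voc <- if (i %% 2 == 0) topic1 else topic2
    sample(voc, 8, replace = TRUE)
  })
  wm <- train_word_model(corpus, word_model_config(dim = 12, window = 2,
                                                   epochs = 25, seed = 4))
  v <- wm$vectors
  expect_true(all(is.finite(v)))
  expect_true(all(sqrt(rowSums(v^2)) > 0))
  expect_lte(nrow(v), 8000) # 20^3 alphabet bound

  cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  cos_same <- mean(apply(utils::combn(topic1, 2), 2,
                         function(w) cosine(v[w[1], ], v[w[2], ])))
  cross <- expand.grid(topic1, topic2, stringsAsFactors = FALSE)
  cos_cross <- mean(apply(cross, 1,
                          function(w) cosine(v[w[1], ], v[w[2], ])))
  expect_gt(cos_same, cos_cross)

  # determinism under a fixed seed
  wm2 <- train_word_model(corpus, word_model_config(dim = 12, window = 2,
                                                    epochs = 25, seed = 4))
  expect_identical(wm$vectors, wm2$vectors)
  expect_error(train_word_model(list(), word_model_config()), "non-empty")
})

test_that("protein embedding is the mean of in-vocabulary word vectors", {
  vecs <- rbind(AAA = c(1, 0, 0), CCC = c(0, 1, 0))
  wm <- structure(list(vectors = vecs,
                       config = word_model_config(dim = 3)),
                  class = "cpi_word_model")
  expect_equal(embed_protein(c("AAA", "AAA"), wm), c(1, 0, 0))
  expect_equal(embed_protein(c("AAA", "CCC"), wm), c(0.5, 0.5, 0))
  expect_equal(embed_protein(c("CCC", "AAA"), wm),
               embed_protein(c("AAA", "CCC"), wm)) # order invariance
  expect_equal(embed_protein("AAACCC", wm), c(0.5, 0.5, 0)) # raw sequence
  # out-of-vocabulary words are skipped; all-OOV is an error
  expect_equal(embed_protein(c("AAA", "ZZZ"), wm), c(1, 0, 0))
  expect_error(embed_protein(c("ZZZ", "WWW"), wm), "feature space")
  # linear in word-vector scaling
  wm2 <- wm; wm2$vectors <- 3 * wm2$vectors
  expect_equal(embed_protein(c("AAA", "CCC"), wm2),
               3 * embed_protein(c("AAA", "CCC"), wm))
})

test_that("pair vectors concatenate compound-first at declared lengths", {
  cv <- rnorm(200); pe <- rnorm(100)
  pv <- build_pair_vector(cv, pe)
  expect_length(pv, 300)
  expect_equal(pv[1:200], cv)
  expect_equal(pv[201:300], pe)
  expect_error(build_pair_vector(rnorm(10), pe), "length 10")
  expect_equal(build_pair_vector(numeric(4), numeric(2),
                                 compound_dim = 4, protein_dim = 2),
               numeric(6))

  pairs <- tibble::tibble(compound_id = c("a", "b"), protein_id = c("p", "p"),
                          label = c("positive", "negative"))
  cs <- matrix(1:4, 2, dimnames = list(c("a", "b"), NULL))
  pe2 <- matrix(5:6, 1, 2, dimnames = list("p", NULL))
  built <- build_pair_matrix(pairs, cs, pe2)
  expect_equal(dim(built$x), c(2, 4))
  expect_equal(built$y, c(1L, 0L))
  expect_error(build_pair_matrix(
    tibble::tibble(compound_id = "zz", protein_id = "p"), cs, pe2), "zz")
})

test_that("featurization is a pure function of its inputs", {
  set.seed(6)
  fps <- purrr::map(1:8, ~ sort(sample.int(32, 8)))
  pca <- fit_compound_pca(fps, n = 3, nbits = 32)
  s1 <- predict(pca, fps)
  s2 <- predict(pca, fps)
  expect_identical(s1, s2)
})
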