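#' Word-model configuration for protein 3-mer embeddings
#'
#' Hyperparameters of the continuous bag-of-words (CBOW) model with negative
#' sampling used to embed protein 3-mer words: 100-dimensional vectors, 5
#' negative samples and a context window of 5, following common practice for
#' sequence k-mer corpora.
#'
#' @param dim Embedding dimension. Default 100.
#' @param window Context window half-width (words on each side). Default 5.
#' @param negative Number of negative samples per target. Default 5.
#' @param epochs Training passes over the corpus. Default 10.
#' @param learning_rate Initial SGD step size, linearly decayed. Default 0.05.
#' @param min_count Minimum corpus frequency for a word to enter the
#'   vocabulary. Default 1.
#' @param workers Declared parallelism. This implementation is
#'   single-threaded; values above 1 are accepted for interface compatibility
#'   but training always runs deterministically on one worker.
#' @param seed Integer seed.
#' @return A list of class `cpi_word_config`.
#' @export
word_model_config <- function(dim = 100, window = 5, negative = 5,
                              epochs = 10, learning_rate = 0.05,
                              min_count = 1, workers = 1, seed = 1L) {
  assert_that(dim > 0, "`dim` must be positive")
  assert_that(window >= 1, "`window` must be >= 1")
  assert_that(negative >= 1, "`negative` must be >= 1")
  structure(
    list(dim = as.integer(dim), window = as.integer(window),
         negative = as.integer(negative), epochs = as.integer(epochs),
         learning_rate = learning_rate, min_count = as.integer(min_count),
         workers = as.integer(workers), seed = as.integer(seed)),
    class = "cpi_word_config"
  )
}

#' Train a CBOW word model on a tokenized protein corpus
#'
#' Learns one vector per 3-mer word by predicting each word from the mean of
#' its context-window word vectors, optimized by stochastic gradient descent
#' with negative sampling (noise distribution proportional to the 3/4 power
#' of word frequency). Deterministic under a fixed seed.
#'
#' @param corpus List of character vectors: each protein's 3-mer words (see
#'   [tokenize_protein()]).
#' @param cfg A [word_model_config()].
#' @return Object of class `cpi_word_model`: list with `vectors` (matrix,
#'   rows = vocabulary words) and `config`.
#' @export
train_word_model <- function(corpus, cfg = word_model_config()) {
  assert_that(is.list(corpus) && length(corpus) > 0, "corpus must be a non-empty list")
  corpus <- lapply(corpus, as.character)
  assert_that(sum(lengths(corpus)) > 0, "corpus has no words")

  freq <- table(unlist(corpus, use.names = FALSE))
  vocab <- names(freq)[freq >= cfg$min_count]
  assert_that(length(vocab) > 0, "no word reaches `min_count`")
  vindex <- stats::setNames(seq_along(vocab), vocab)
  docs <- lapply(corpus, function(w) unname(vindex[w[w %in% vocab]]))
  docs <- docs[lengths(docs) > 0]

  nv <- length(vocab)
  d <- cfg$dim
  # unigram^(3/4) noise distribution
  noise <- as.numeric(freq[vocab])^0.75
  noise <- noise / sum(noise)

  with_seed(cfg$seed, {
    u <- matrix(stats::runif(nv * d, -0.5, 0.5) / d, nrow = nv) # input vectors
    v <- matrix(0, nrow = nv, ncol = d)                         # output vectors

    total_steps <- cfg$epochs * sum(lengths(docs))
    step <- 0L
    for (epoch in seq_len(cfg$epochs)) {
      for (doc in docs) {
        len <- length(doc)
        for (t in seq_len(len)) {
          step <- step + 1L
          lr <- cfg$learning_rate * max(1 - step / total_steps, 1e-4)
          lo <- max(1L, t - cfg$window)
          hi <- min(len, t + cfg$window)
          ctx <- doc[c(lo:hi)[c(lo:hi) != t]]
          if (length(ctx) == 0) next
          h <- colMeans(u[ctx, , drop = FALSE])
          targets <- c(doc[t], sample.int(nv, cfg$negative, replace = TRUE, prob = noise))
          lab <- c(1, numeric(cfg$negative))
          vt <- v[targets, , drop = FALSE]
          s <- stats::plogis(as.numeric(vt %*% h))
          g <- (lab - s) * lr
          grad_h <- as.numeric(crossprod(vt, g))
          v[targets, ] <- vt + outer(g, h)
          u[ctx, ] <- u[ctx, , drop = FALSE] +
            matrix(grad_h / length(ctx), nrow = length(ctx), ncol = d, byrow = TRUE)
        }
      }
    }
    rownames(u) <- vocab
    structure(list(vectors = u, config = cfg), class = "cpi_word_model")
  })
}

#' @export
print.cpi_word_model <- function(x, ...) {
  cat(sprintf("CBOW 3-mer word model: %d words x %d dimensions\n",
              nrow(x$vectors), ncol(x$vectors)))
  invisible(x)
}

#' @export
tidy.cpi_word_model <- function(x, ...) {
  tibble::tibble(
    word = rownames(x$vectors),
    norm = sqrt(rowSums(x$vectors^2))
  )
}
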