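#' Network specification for the fully connected CPI classifier
#'
#' Two hidden layers (affine, batch normalization, ReLU, dropout), then an
#' affine layer with a sigmoid output. The default grids searched over the
#' architecture are exposed by [default_grids()].
#'
#' @param h1,h2 Neurons in the first and second hidden layer.
#' @param dropout Dropout rate in both hidden blocks.
#' @param learning_rate Adam step size.
#' @param epochs Training epochs.
#' @param input_dim Input feature dimension. Default 300 (200 compound + 100
#'   protein features).
#' @param batch_size Minibatch size. Default 256.
#' @param seed Integer seed for weight initialization and batch shuffling.
#' @return A list of class `cpi_network_spec`.
#' @export
network_spec <- function(h1 = 256, h2 = 128, dropout = 0.2,
                         learning_rate = 0.001, epochs = 100,
                         input_dim = 300, batch_size = 256, seed = 1L) {
  assert_that(h1 >= 1 && h2 >= 1, "hidden sizes must be positive")
  assert_that(dropout >= 0 && dropout < 1, "`dropout` must be in [0, 1)")
  assert_that(learning_rate > 0, "`learning_rate` must be positive")
  assert_that(epochs >= 1, "`epochs` must be >= 1")
  structure(
    list(h1 = as.integer(h1), h2 = as.integer(h2), dropout = dropout,
         learning_rate = learning_rate, epochs = as.integer(epochs),
         input_dim = as.integer(input_dim), batch_size = as.integer(batch_size),
         seed = as.integer(seed)),
    class = "cpi_network_spec"
  )
}

#' Hyperparameter grids for model selection
#'
#' The searched ranges: first hidden layer \{256, 512, 1024, 2048\}, second
#' hidden layer \{128, 256, 512, 1024\}, dropout \{0, 0.2, 0.5\}, learning
#' rate \{0.01, 0.001, 0.0001\} and epochs \{100, 200, 500\} - a Cartesian
#' product of 432 candidate models.
#'
#' @return Named list of grid vectors.
#' @export
default_grids <- function() {
  list(
    h1 = c(256L, 512L, 1024L, 2048L),
    h2 = c(128L, 256L, 512L, 1024L),
    dropout = c(0, 0.2, 0.5),
    learning_rate = c(0.01, 0.001, 0.0001),
    epochs = c(100L, 200L, 500L)
  )
}

#' Enumerate all candidate specifications of a hyperparameter grid
#'
#' @param grids Named list of grid vectors, as in [default_grids()].
#' @return Tibble with one row per combination, in enumeration order (first
#'   grid varies slowest).
#' @export
grid_candidates <- function(grids = default_grids()) {
  assert_that(is.list(grids) && length(grids) > 0 && all(lengths(grids) > 0),
              "grids must be a non-empty named list of non-empty vectors")
  do.call(tidyr::expand_grid, grids)
}

#' Binary cross-entropy loss
#'
#' `-(1/n) * sum(y*log(p) + (1-y)*log(1-p))` with predictions clipped to
#' `(eps, 1-eps)` so perfect 0/1 outputs do not produce infinities.
#'
#' @param y Binary labels (0/1).
#' @param yhat Predicted probabilities.
#' @param eps Clipping constant. Default 1e-7.
#' @return Non-negative scalar.
#' @export
bce_loss <- function(y, yhat, eps = 1e-7) {
  assert_that(length(y) > 0 && length(y) == length(yhat),
              "empty batch or length mismatch in bce_loss")
  p <- pmin(pmax(yhat, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# --- internal network plumbing ------------------------------------------------

# He-uniform initialization for one affine layer
init_affine <- function(n_in, n_out) {
  lim <- sqrt(6 / n_in)
  list(W = matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out),
       b = numeric(n_out))
}

init_bn <- function(n) {
  list(gamma = rep(1, n), beta = numeric(n),
       run_mean = numeric(n), run_var = rep(1, n))
}

#' Build an untrained network from a specification
#'
#' Layer order per hidden block: affine, batch normalization, ReLU, dropout;
#' the head is affine plus sigmoid. Weights use He-uniform initialization
#' under the spec seed.
#'
#' @param spec A [network_spec()].
#' @return A list of class `cpi_network` holding parameters and the spec.
#' @export
build_network <- function(spec) {
  with_seed(derive_seed(spec$seed, "init"), {
    structure(
      list(
        l1 = init_affine(spec$input_dim, spec$h1), bn1 = init_bn(spec$h1),
        l2 = init_affine(spec$h1, spec$h2), bn2 = init_bn(spec$h2),
        l3 = init_affine(spec$h2, 1L),
        spec = spec
      ),
      class = "cpi_network"
    )
  })
}

# number of affine parameters (weights + biases), excluding BN parameters
n_affine_params <- function(net) {
  s <- net$spec
  s$input_dim * s$h1 + s$h1 + s$h1 * s$h2 + s$h2 + s$h2 + 1L
}

.bn_eps <- 1e-5
.bn_momentum <- 0.9

bn_forward_train <- function(z, bn) {
  m <- colMeans(z)
  v <- colMeans(sweep(z, 2, m)^2)
  zc <- sweep(z, 2, m)
  inv_sd <- 1 / sqrt(v + .bn_eps)
  zhat <- sweep(zc, 2, inv_sd, "*")
  out <- sweep(sweep(zhat, 2, bn$gamma, "*"), 2, bn$beta, "+")
  bn$run_mean <- .bn_momentum * bn$run_mean + (1 - .bn_momentum) * m
  bn$run_var <- .bn_momentum * bn$run_var + (1 - .bn_momentum) * v
  list(out = out, zhat = zhat, inv_sd = inv_sd, bn = bn)
}

bn_forward_eval <- function(z, bn) {
  zhat <- sweep(sweep(z, 2, bn$run_mean), 2, 1 / sqrt(bn$run_var + .bn_eps), "*")
  sweep(sweep(zhat, 2, bn$gamma, "*"), 2, bn$beta, "+")
}

bn_backward <- function(dout, cache, bn) {
  m <- nrow(dout)
  dgamma <- colSums(dout * cache$zhat)
  dbeta <- colSums(dout)
  dzhat <- sweep(dout, 2, bn$gamma, "*")
  t1 <- sweep(dzhat, 2, colMeans(dzhat))
  t2 <- sweep(cache$zhat, 2, colMeans(dzhat * cache$zhat), "*")
  dz <- sweep(t1 - t2, 2, cache$inv_sd, "*")
  list(dz = dz, dgamma = dgamma, dbeta = dbeta)
}

# forward pass in evaluation mode (running BN statistics, no dropout)
forward_eval <- function(net, x) {
  a1 <- pmax(bn_forward_eval(x %*% net$l1$W + rep(1, nrow(x)) %o% net$l1$b, net$bn1), 0)
  a2 <- pmax(bn_forward_eval(a1 %*% net$l2$W + rep(1, nrow(a1)) %o% net$l2$b, net$bn2), 0)
  as.numeric(stats::plogis(a2 %*% net$l3$W + net$l3$b))
}

adam_new <- function(shape_list) {
  lapply(shape_list, function(p) list(m = p * 0, v = p * 0))
}

adam_update <- function(param, grad, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^t)
  vhat <- state$v / (1 - beta2^t)
  list(param = param - lr * mhat / (sqrt(vhat) + eps), state = state)
}

#' Train the fully connected classifier
#'
#' Minibatch training with the Adam optimizer and binary cross-entropy loss.
#' Batch statistics are used for normalization during training and running
#' averages at prediction time; dropout is inverted (no rescaling needed at
#' inference). Training aborts with a diagnostic if the loss becomes
#' non-finite.
#'
#' @param x Numeric feature matrix (rows = pairs).
#' @param y Binary labels (0/1).
#' @param spec A [network_spec()].
#' @param verbose Print the loss every few epochs.
#' @return Object of class `cpi_dnn`: the trained network plus a per-epoch
#'   loss `history` and input normalization statistics.
#' @export
train_network <- function(x, y, spec = network_spec(), verbose = FALSE) {
  assert_that(is.matrix(x) && nrow(x) == length(y),
              "features and labels are misaligned")
  assert_that(all(y %in% c(0, 1)), "labels must be 0/1")
  assert_that(ncol(x) == spec$input_dim,
              sprintf("x has %d columns but spec$input_dim is %d", ncol(x), spec$input_dim))

  # standardize inputs with training statistics
  mu <- colMeans(x)
  sg <- apply(x, 2, stats::sd)
  sg[sg < 1e-12] <- 1
  xs <- sweep(sweep(x, 2, mu), 2, sg, "/")

  net <- build_network(spec)
  params <- list(W1 = net$l1$W, b1 = net$l1$b, g1 = net$bn1$gamma, be1 = net$bn1$beta,
                 W2 = net$l2$W, b2 = net$l2$b, g2 = net$bn2$gamma, be2 = net$bn2$beta,
                 W3 = net$l3$W, b3 = net$l3$b)
  opt <- adam_new(params)
  n <- nrow(xs)
  history <- numeric(spec$epochs)
  t_step <- 0L

  with_seed(derive_seed(spec$seed, "train"), {
    for (epoch in seq_len(spec$epochs)) {
      ord <- sample.int(n)
      batch_starts <- seq(1L, n, by = spec$batch_size)
      ep_loss <- 0
      for (bs in batch_starts) {
        idx <- ord[bs:min(bs + spec$batch_size - 1L, n)]
        if (length(idx) < 2L) next # BN needs at least two rows
        xb <- xs[idx, , drop = FALSE]
        yb <- y[idx]
        m <- length(idx)

        # forward
        z1 <- xb %*% params$W1 + rep(1, m) %o% params$b1
        bn1 <- bn_forward_train(z1, list(gamma = params$g1, beta = params$be1,
                                         run_mean = net$bn1$run_mean,
                                         run_var = net$bn1$run_var))
        net$bn1$run_mean <- bn1$bn$run_mean; net$bn1$run_var <- bn1$bn$run_var
        a1 <- pmax(bn1$out, 0)
        d1 <- if (spec$dropout > 0) {
          (matrix(stats::runif(m * spec$h1), m) >= spec$dropout) / (1 - spec$dropout)
        } else 1
        a1d <- a1 * d1

        z2 <- a1d %*% params$W2 + rep(1, m) %o% params$b2
        bn2 <- bn_forward_train(z2, list(gamma = params$g2, beta = params$be2,
                                         run_mean = net$bn2$run_mean,
                                         run_var = net$bn2$run_var))
        net$bn2$run_mean <- bn2$bn$run_mean; net$bn2$run_var <- bn2$bn$run_var
        a2 <- pmax(bn2$out, 0)
        d2 <- if (spec$dropout > 0) {
          (matrix(stats::runif(m * spec$h2), m) >= spec$dropout) / (1 - spec$dropout)
        } else 1
        a2d <- a2 * d2

        p <- as.numeric(stats::plogis(a2d %*% params$W3 + params$b3))
        loss <- bce_loss(yb, p)
        if (!is.finite(loss)) {
          rlang::abort(sprintf(
            "training diverged: non-finite loss at epoch %d (learning rate %g)",
            epoch, spec$learning_rate))
        }
        ep_loss <- ep_loss + loss * m

        # backward
        dlogit <- matrix((p - yb) / m, ncol = 1)
        gW3 <- crossprod(a2d, dlogit)
        gb3 <- sum(dlogit)
        da2d <- dlogit %*% t(params$W3)
        da2 <- (da2d * d2) * (a2 > 0)
        bb2 <- bn_backward(da2, bn2, list(gamma = params$g2))
        dz2 <- bb2$dz
        gW2 <- crossprod(a1d, dz2)
        gb2 <- colSums(dz2)
        da1d <- dz2 %*% t(params$W2)
        da1 <- (da1d * d1) * (a1 > 0)
        bb1 <- bn_backward(da1, bn1, list(gamma = params$g1))
        dz1 <- bb1$dz
        gW1 <- crossprod(xb, dz1)
        gb1 <- colSums(dz1)

        grads <- list(W1 = gW1, b1 = gb1, g1 = bb1$dgamma, be1 = bb1$dbeta,
                      W2 = gW2, b2 = gb2, g2 = bb2$dgamma, be2 = bb2$dbeta,
                      W3 = gW3, b3 = gb3)
        t_step <- t_step + 1L
        for (k in names(params)) {
          upd <- adam_update(params[[k]], grads[[k]], opt[[k]],
                             spec$learning_rate, t_step)
          params[[k]] <- upd$param
          opt[[k]] <- upd$state
        }
      }
      history[epoch] <- ep_loss / n
      if (verbose && (epoch %% 10 == 0 || epoch == 1)) {
        message(sprintf("epoch %d/%d loss %.4f", epoch, spec$epochs, history[epoch]))
      }
    }
  })

  net$l1$W <- params$W1; net$l1$b <- params$b1
  net$bn1$gamma <- params$g1; net$bn1$beta <- params$be1
  net$l2$W <- params$W2; net$l2$b <- params$b2
  net$bn2$gamma <- params$g2; net$bn2$beta <- params$be2
  net$l3$W <- params$W3; net$l3$b <- params$b3

  structure(
    list(network = net, spec = spec,
         norm = list(mean = mu, sd = sg),
         history = tibble::tibble(epoch = seq_len(spec$epochs), loss = history)),
    class = "cpi_dnn"
  )
}

#' Predict interaction probabilities
#'
#' @param object A trained `cpi_dnn`.
#' @param newdata Feature matrix with the model's input dimension.
#' @param cutoff Probability cutoff; a probability at the cutoff is called
#'   positive (inclusive rule). Default 0.5.
#' @param ... Unused.
#' @return Tibble with `prob` in (0, 1) and binary `label`.
#' @export
predict.cpi_dnn <- function(object, newdata, cutoff = 0.5, ...) {
  assert_that(is.matrix(newdata) && ncol(newdata) == object$spec$input_dim,
              sprintf("newdata must have %d columns", object$spec$input_dim))
  xs <- sweep(sweep(newdata, 2, object$norm$mean), 2, object$norm$sd, "/")
  p <- forward_eval(object$network, xs)
  tibble::tibble(prob = p, label = as.integer(p >= cutoff))
}

#' @export
print.cpi_dnn <- function(x, ...) {
  s <- x$spec
  cat(sprintf(
    "CPI classifier: %d-%d-%d-1 (dropout %.1f, lr %g, %d epochs); final loss %.4f\n",
    s$input_dim, s$h1, s$h2, s$dropout, s$learning_rate, s$epochs,
    tail(x$history$loss, 1)))
  invisible(x)
}

#' @export
tidy.cpi_dnn <- function(x, ...) {
  x$history
}

#' @export
glance.cpi_dnn <- function(x, ...) {
  s <- x$spec
  tibble::tibble(
    h1 = s$h1, h2 = s$h2, dropout = s$dropout,
    learning_rate = s$learning_rate, epochs = s$epochs,
    n_parameters = n_affine_params(x$network),
    final_loss = tail(x$history$loss, 1)
  )
}

#' Grid search over network hyperparameters by cross-validated accuracy
#'
#' Evaluates every combination in the Cartesian product of the grids with
#' k-fold cross validation on the supplied training data and returns the
#' specification with the highest mean accuracy (ties broken by enumeration
#' order).
#'
#' @param x,y Training features and 0/1 labels.
#' @param grids Named list of grid vectors (see [default_grids()]).
#' @param folds Number of cross-validation folds. Default 5.
#' @param batch_size,seed Passed to each fitted [network_spec()].
#' @param verbose Print progress.
#' @return List with `best_spec` (a [network_spec()]) and `results` (tibble:
#'   one row per combination with mean CV accuracy and AUROC).
#' @export
grid_search <- function(x, y, grids = default_grids(), folds = 5,
                        batch_size = 256, seed = 1L, verbose = FALSE) {
  cand <- grid_candidates(grids)
  assert_that(nrow(cand) > 0, "empty hyperparameter grid")
  n <- nrow(x)
  fold_id <- with_seed(derive_seed(seed, "cv"),
                       sample(rep_len(seq_len(folds), n)))
  res <- purrr::pmap(cand, function(h1, h2, dropout, learning_rate, epochs) {
    accs <- numeric(folds)
    aucs <- numeric(folds)
    for (k in seq_len(folds)) {
      tr <- fold_id != k
      spec <- network_spec(h1 = h1, h2 = h2, dropout = dropout,
                           learning_rate = learning_rate, epochs = epochs,
                           input_dim = ncol(x), batch_size = batch_size,
                           seed = seed)
      fit <- train_network(x[tr, , drop = FALSE], y[tr], spec)
      pr <- predict(fit, x[!tr, , drop = FALSE])
      accs[k] <- mean(pr$label == y[!tr])
      aucs[k] <- if (length(unique(y[!tr])) == 2L) auroc(y[!tr], pr$prob) else NA_real_
    }
    if (verbose) {
      message(sprintf("h1=%d h2=%d drop=%.1f lr=%g ep=%d: acc %.4f",
                      h1, h2, dropout, learning_rate, epochs, mean(accs)))
    }
    tibble::tibble(h1 = h1, h2 = h2, dropout = dropout,
                   learning_rate = learning_rate, epochs = epochs,
                   cv_accuracy = mean(accs), cv_auroc = mean(aucs))
  }) |> purrr::list_rbind()

  best <- res[which.max(res$cv_accuracy), ]
  best_spec <- network_spec(h1 = best$h1, h2 = best$h2, dropout = best$dropout,
                            learning_rate = best$learning_rate,
                            epochs = best$epochs, input_dim = ncol(x),
                            batch_size = batch_size, seed = seed)
  list(best_spec = best_spec, results = res)
}
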