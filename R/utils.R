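# Internal helpers shared across modules.

# stopifnot-style assertion with a readable message
assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) rlang::abort(msg)
  invisible(TRUE)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Derive a child seed from a base seed and a stage tag, keeping the result
# inside the 32-bit integer range R requires.
derive_seed <- function(seed, tag) {
  stopifnot(is_scalar_number(seed))
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}

# Run code under a temporary RNG state so callers' streams are untouched.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Convert a list of on-bit index vectors into a sparse pattern matrix
# (rows = molecules, columns = bit positions).
fp_sparse_matrix <- function(fps, nbits) {
  lens <- lengths(fps)
  Matrix::sparseMatrix(
    i = rep.int(seq_along(fps), lens),
    j = unlist(fps, use.names = FALSE),
    dims = c(length(fps), nbits),
    x = 1
  )
}

# Dense 0/1 matrix from on-bit index lists (for PCA).
fp_dense_matrix <- function(fps, nbits) {
  m <- matrix(0, nrow = length(fps), ncol = nbits)
  for (i in seq_along(fps)) m[i, fps[[i]]] <- 1
  m
}
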