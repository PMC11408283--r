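#' Morgan fingerprints from SMILES
#'
#' Computes hashed circular (Morgan/ECFP-style) fingerprints of radius 2
#' folded to a fixed bit length, delegating the chemistry to the RDKit
#' toolkit through the `python` interpreter on the PATH. SMILES are
#' canonicalized by the parser, so two spellings of the same molecule yield
#' the same fingerprint.
#'
#' @param smiles Character vector of SMILES strings.
#' @param radius Circular neighborhood radius. Default 2.
#' @param nbits Folded fingerprint length. Default 2048.
#' @return A named list of sorted integer vectors of on-bit positions
#'   (1-based). Errors name the first unparseable record.
#' @export
morgan_fingerprint <- function(smiles, radius = 2, nbits = 2048) {
  assert_that(length(smiles) > 0, "no SMILES given")
  py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  assert_that(nzchar(py), "no `python` interpreter with RDKit found on PATH")

  infile <- tempfile("smiles-", fileext = ".txt")
  outfile <- tempfile("fp-", fileext = ".txt")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  writeLines(smiles, infile)

  script <- sprintf(
    "import sys
from rdkit import Chem
from rdkit.Chem import rdMolDescriptors
from rdkit import RDLogger
RDLogger.DisableLog('rdApp.*')
radius, nbits = %d, %d
out = open(sys.argv[2], 'w')
for line in open(sys.argv[1]):
    smi = line.rstrip('\\n')
    mol = Chem.MolFromSmiles(smi)
    if mol is None:
        out.write('ERROR\\n')
    else:
        fp = rdMolDescriptors.GetMorganFingerprintAsBitVect(mol, radius, nBits=nbits)
        out.write(' '.join(str(b) for b in fp.GetOnBits()) + '\\n')
out.close()
", as.integer(radius), as.integer(nbits))
  status <- system2(py, c("-c", shQuote(script), shQuote(infile), shQuote(outfile)),
                    stdout = FALSE, stderr = FALSE)
  assert_that(status == 0 && file.exists(outfile),
              "RDKit fingerprint computation failed (is rdkit installed for `python`?)")
  lines <- readLines(outfile)
  assert_that(length(lines) == length(smiles), "fingerprint output truncated")
  bad <- which(lines == "ERROR")
  if (length(bad) > 0) {
    rlang::abort(sprintf("unparseable SMILES at record %d: %s",
                         bad[1], smiles[bad[1]]))
  }
  out <- lapply(lines, function(l) {
    if (!nzchar(l)) integer(0) else sort(as.integer(strsplit(l, " ")[[1]]) + 1L)
  })
  names(out) <- names(smiles)
  out
}

#' Fit a PCA reduction of compound fingerprints
#'
#' Principal components of the centered fingerprint bit matrix; the top `n`
#' components (default 200) become the compound feature representation. When
#' `n` exceeds the matrix rank the model is truncated with a warning.
#'
#' @param fingerprints List of on-bit index vectors, or a numeric 0/1 matrix
#'   (rows = compounds).
#' @param n Number of components to retain. Default 200.
#' @param nbits Fingerprint length when `fingerprints` is a list.
#' @return An object of class `cpi_pca` with elements `center`, `rotation`,
#'   `sdev`, `n_components`.
#' @export
fit_compound_pca <- function(fingerprints, n = 200, nbits = 2048) {
  x <- if (is.matrix(fingerprints)) fingerprints else fp_dense_matrix(fingerprints, nbits)
  assert_that(nrow(x) >= 2, "need at least two compounds to fit a PCA")
  max_rank <- min(nrow(x) - 1L, ncol(x))
  if (n > max_rank) {
    rlang::warn(sprintf("requested %d components exceeds rank %d; truncating", n, max_rank))
    n <- max_rank
  }
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n)
  structure(
    list(center = p$center, rotation = p$rotation,
         sdev = p$sdev, n_components = ncol(p$rotation)),
    class = "cpi_pca"
  )
}

#' @export
print.cpi_pca <- function(x, ...) {
  cat(sprintf("Compound fingerprint PCA: %d components over %d bits\n",
              x$n_components, length(x$center)))
  invisible(x)
}

#' @rdname fit_compound_pca
#' @param object A fitted `cpi_pca`.
#' @param newdata List of on-bit index vectors or a 0/1 matrix.
#' @param ... Unused.
#' @export
predict.cpi_pca <- function(object, newdata, ...) {
  x <- if (is.matrix(newdata)) newdata else fp_dense_matrix(newdata, length(object$center))
  assert_that(ncol(x) == length(object$center),
              "fingerprint bit length differs from the fitted model")
  scores <- sweep(x, 2, object$center) %*% object$rotation
  colnames(scores) <- colnames(object$rotation)
  if (!is.matrix(newdata) && !is.null(names(newdata))) rownames(scores) <- names(newdata)
  scores
}

#' @export
tidy.cpi_pca <- function(x, ...) {
  v <- x$sdev^2
  tibble::tibble(
    component = seq_along(v),
    variance = v,
    prop_variance = v / sum(v)
  )
}

#' Tokenize a protein sequence into non-overlapping 3-mer words
#'
#' A protein sequence is read as a document whose words are consecutive
#' non-overlapping triplets of residues, in the single reading frame starting
#' at the first residue; 1-2 trailing residues are dropped.
#'
#' @param sequence A single amino-acid string (length >= 3).
#' @return Character vector of `floor(nchar/3)` 3-mers.
#' @export
tokenize_protein <- function(sequence) {
  assert_that(is.character(sequence) && length(sequence) == 1L,
              "`sequence` must be a single string")
  len <- nchar(sequence)
  assert_that(len >= 3, "sequence shorter than one 3-mer word")
  n_words <- len %/% 3L
  starts <- 3L * (seq_len(n_words) - 1L) + 1L
  substring(sequence, starts, starts + 2L)
}

#' Average 3-mer embeddings into a protein feature vector
#'
#' The protein representation is the arithmetic mean of the word vectors of
#' its 3-mer words. Out-of-vocabulary words are skipped; a protein with no
#' in-vocabulary word has no representation and raises an error.
#'
#' @param sequence Amino-acid string, or a pre-tokenized character vector of
#'   3-mers.
#' @param word_model A fitted [train_word_model()] object.
#' @return Numeric vector of length `word_model$config$dim`.
#' @export
embed_protein <- function(sequence, word_model) {
  words <- if (length(sequence) == 1L && nchar(sequence[1]) > 3L) {
    tokenize_protein(sequence)
  } else {
    as.character(sequence)
  }
  vecs <- word_model$vectors
  words <- words[words %in% rownames(vecs)]
  assert_that(length(words) > 0,
              "protein has no in-vocabulary 3-mer word; outside the feature space")
  colMeans(vecs[words, , drop = FALSE])
}

#' Embed many proteins at once
#'
#' @param proteins Tibble with columns `protein_id` and `sequence`.
#' @param word_model A fitted [train_word_model()] object.
#' @return Numeric matrix (rows = proteins, named) of embeddings.
#' @export
embed_proteins <- function(proteins, word_model) {
  assert_that(all(c("protein_id", "sequence") %in% names(proteins)),
              "`proteins` needs columns protein_id, sequence")
  emb <- vapply(proteins$sequence, function(s) embed_protein(s, word_model),
                numeric(word_model$config$dim))
  emb <- t(emb)
  dimnames(emb) <- list(proteins$protein_id,
                        paste0("e", seq_len(word_model$config$dim)))
  emb
}

#' Concatenate compound and protein features into a pair vector
#'
#' @param cv Compound feature vector (PCA scores), length `compound_dim`.
#' @param pe Protein embedding, length `protein_dim`.
#' @param label Optional label attached as an attribute.
#' @param compound_dim,protein_dim Expected block lengths (defaults 200 and
#'   100, giving the 300-dimensional pair vector).
#' @return Numeric vector of length `compound_dim + protein_dim`, compound
#'   block first.
#' @export
build_pair_vector <- function(cv, pe, label = NULL,
                              compound_dim = 200, protein_dim = 100) {
  assert_that(length(cv) == compound_dim,
              sprintf("compound block has length %d, expected %d", length(cv), compound_dim))
  assert_that(length(pe) == protein_dim,
              sprintf("protein block has length %d, expected %d", length(pe), protein_dim))
  out <- c(as.numeric(cv), as.numeric(pe))
  if (!is.null(label)) attr(out, "label") <- label
  out
}

#' Build the pair feature matrix for a set of labeled pairs
#'
#' Rows are pairs; columns are the compound PCA scores followed by the
#' protein embedding dimensions.
#'
#' @param pairs Tibble with `compound_id`, `protein_id` and optionally
#'   `label` (`"positive"`/`"negative"`).
#' @param compound_scores Matrix of compound features with compound ids as
#'   row names.
#' @param protein_embeddings Matrix of protein embeddings with protein ids as
#'   row names.
#' @return List with `x` (feature matrix), `y` (0/1 labels or `NULL`), and
#'   `pairs`.
#' @export
build_pair_matrix <- function(pairs, compound_scores, protein_embeddings) {
  missing_c <- setdiff(pairs$compound_id, rownames(compound_scores))
  missing_p <- setdiff(pairs$protein_id, rownames(protein_embeddings))
  assert_that(length(missing_c) == 0,
              sprintf("%d compound(s) lack feature rows (e.g. %s)",
                      length(missing_c), missing_c[1]))
  assert_that(length(missing_p) == 0,
              sprintf("%d protein(s) lack embedding rows (e.g. %s)",
                      length(missing_p), missing_p[1]))
  x <- cbind(compound_scores[pairs$compound_id, , drop = FALSE],
             protein_embeddings[pairs$protein_id, , drop = FALSE])
  rownames(x) <- paste(pairs$compound_id, pairs$protein_id, sep = "|")
  y <- if ("label" %in% names(pairs)) as.integer(pairs$label == "positive") else NULL
  list(x = x, y = y, pairs = pairs)
}
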