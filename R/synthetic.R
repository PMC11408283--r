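#' Configuration of the synthetic CPI benchmark generator
#'
#' The generator plants a low-dimensional latent interaction signal: every
#' compound carries a latent vector `u` expressed in its fingerprint bit
#' probabilities, every protein a latent `v` expressed in its 3-mer word
#' frequencies, and a pair interacts with probability
#' `logistic(u . v / temperature)`. Multi-source records, conflicting labels,
#' near-duplicate ligands and per-protein negative excess emulate the
#' artifacts the curation rules exist for.
#'
#' @param n_compounds Base compounds (twins come on top). Default 2000.
#' @param n_proteins Proteins. Default 50.
#' @param latent_dim Latent interaction dimension. Default 4.
#' @param interaction_temperature Logistic temperature; smaller = cleaner
#'   labels. Default 0.3.
#' @param label_noise_rate Per-record probability that the sampled potency
#'   contradicts the ground truth. Default 0.02.
#' @param near_duplicate_rate Fraction of compounds that receive a structural
#'   twin with Tanimoto > 0.8 (exercises ligand deduplication). Default 0.05.
#' @param multi_source_rate Fraction of pairs duplicated in a second source
#'   with value jitter (exercises the min-value and any-active rules).
#'   Default 0.2.
#' @param observed_fraction Fraction of compound-protein pairs with at least
#'   one measured record. Bioactivity matrices are sparse: most pairs are
#'   never assayed. Default 0.3.
#' @param protein_length_range Sequence length bounds (residues). Default
#'   c(240, 600).
#' @param nbits Fingerprint length. Default 2048.
#' @param seed Integer master seed; every stage derives its own stream.
#' @return A list of class `cpi_generator_config`.
#' @export
generator_config <- function(n_compounds = 2000, n_proteins = 50,
                             latent_dim = 4, interaction_temperature = 0.3,
                             label_noise_rate = 0.02,
                             near_duplicate_rate = 0.05,
                             multi_source_rate = 0.2,
                             observed_fraction = 0.3,
                             protein_length_range = c(240, 600),
                             nbits = 2048, seed = 1L) {
  rates <- c(label_noise_rate, near_duplicate_rate, multi_source_rate,
             observed_fraction)
  assert_that(all(rates >= 0 & rates <= 1), "rates must be in [0, 1]")
  assert_that(latent_dim >= 1, "`latent_dim` must be >= 1")
  assert_that(length(protein_length_range) == 2 && protein_length_range[1] >= 9,
              "`protein_length_range` must be a length-2 vector with min >= 9")
  structure(
    list(n_compounds = as.integer(n_compounds),
         n_proteins = as.integer(n_proteins),
         latent_dim = as.integer(latent_dim),
         interaction_temperature = interaction_temperature,
         label_noise_rate = label_noise_rate,
         near_duplicate_rate = near_duplicate_rate,
         multi_source_rate = multi_source_rate,
         observed_fraction = observed_fraction,
         protein_length_range = as.integer(protein_length_range),
         nbits = as.integer(nbits),
         seed = as.integer(seed)),
    class = "cpi_generator_config"
  )
}

# Deterministic word scheme: signal 3-mers tied to a latent dimension and
# polarity, plus background words. Shared by training and external proteins.
make_word_scheme <- function(cfg, words_per_group = 6, n_background = 60) {
  with_seed(derive_seed(cfg$seed, "vocab"), {
    n_signal <- cfg$latent_dim * 2L * words_per_group
    total <- n_signal + n_background
    words <- character(0)
    while (length(words) < total) {
      cand <- paste0(sample(.aa20, 3 * (total - length(words)) * 2, replace = TRUE) |>
                       matrix(ncol = 3) |>
                       apply(1, paste0, collapse = ""))
      words <- unique(c(words, cand))[seq_len(min(total, length(unique(c(words, cand)))))]
    }
    words <- words[seq_len(total)]
    tibble::tibble(
      word = words,
      dim = c(rep(seq_len(cfg$latent_dim), each = 2L * words_per_group),
              rep(0L, n_background)),
      sign = c(rep(rep(c(1L, -1L), each = words_per_group), cfg$latent_dim),
               rep(0L, n_background))
    )
  })
}

#' Generate synthetic compounds with a planted latent signal
#'
#' Each compound draws a latent vector `u`; fingerprint bit probabilities are
#' logistic in a sparse linear map of `u`, so PCA on the bit matrix recovers
#' the latent coordinates. A `near_duplicate_rate` fraction of compounds get
#' a structural twin (5% of on-bits swapped), guaranteeing Tanimoto > 0.8
#' pairs for the deduplication rule.
#'
#' @param cfg A [generator_config()].
#' @return Tibble: `compound_id`, `mol_weight_Da`, `fingerprint` (list of
#'   on-bit indices), `latent` (list), `twin_of` (`NA` or the base id).
#' @export
generate_compounds <- function(cfg = generator_config()) {
  with_seed(derive_seed(cfg$seed, "compounds"), {
    n <- cfg$n_compounds
    d <- cfg$latent_dim
    u <- matrix(stats::rnorm(n * d), n, d)

    # sparse loading map: half the bits carry signal from one latent dim
    base_logit <- stats::qlogis(0.08)
    w <- matrix(0, d, cfg$nbits)
    signal_bits <- sample.int(cfg$nbits, cfg$nbits %/% 2)
    w[cbind(sample.int(d, length(signal_bits), replace = TRUE), signal_bits)] <-
      sample(c(-2, 2), length(signal_bits), replace = TRUE)
    probs <- stats::plogis(base_logit + u %*% w)
    bits <- matrix(stats::runif(n * cfg$nbits), n, cfg$nbits) < probs
    fps <- apply(bits, 1, which, simplify = FALSE)

    ids <- sprintf("C%05d", seq_len(n))
    out <- tibble::tibble(
      compound_id = ids,
      mol_weight_Da = stats::runif(n, 120, 950),
      fingerprint = fps,
      latent = lapply(seq_len(n), function(i) u[i, ]),
      twin_of = NA_character_
    )

    n_twin <- round(cfg$near_duplicate_rate * n)
    if (n_twin > 0) {
      base_idx <- sample.int(n, n_twin)
      twins <- purrr::map(base_idx, function(i) {
        fp <- out$fingerprint[[i]]
        k <- max(1L, round(0.05 * length(fp)))
        dropped <- sample(fp, k)
        added <- sample(setdiff(seq_len(cfg$nbits), fp), k)
        sort(c(setdiff(fp, dropped), added))
      })
      out <- dplyr::bind_rows(out, tibble::tibble(
        compound_id = sprintf("C%05dT", base_idx),
        mol_weight_Da = out$mol_weight_Da[base_idx],
        fingerprint = twins,
        latent = out$latent[base_idx],
        twin_of = out$compound_id[base_idx]
      ))
    }
    out
  })
}

#' Generate synthetic proteins with a planted latent signal
#'
#' Each protein draws a latent vector `v`; its sequence is a chain of 3-mer
#' words sampled from a vocabulary whose signal words are tied to one latent
#' dimension and polarity, with sampling weight `exp(sign * v_dim)`. Word
#' frequencies therefore encode `v`, so averaged word embeddings correlate
#' with it.
#'
#' @param cfg A [generator_config()].
#' @param latents Optional matrix of latent vectors (rows = proteins);
#'   defaults to standard normal draws.
#' @param ids Optional protein ids.
#' @param scheme Word scheme from `make_word_scheme()` (defaults to the
#'   scheme determined by the config seed, shared across calls).
#' @param stream Seed stream tag (change to draw distinct proteins from the
#'   same config).
#' @param signal_strength Multiplier on the latent signal in the word
#'   weights; below 1 blurs the sequence-level encoding of `v`. Default 1.
#' @param background_bias Optional multiplier vector over the background
#'   words (recycled), shifting the background composition - used to emulate
#'   a protein family with sequence statistics unlike the training corpus.
#' @return Tibble: `protein_id`, `sequence`, `latent` (list).
#' @export
generate_proteins <- function(cfg = generator_config(), latents = NULL,
                              ids = NULL, scheme = NULL, stream = "proteins",
                              signal_strength = 1, background_bias = NULL) {
  if (is.null(scheme)) scheme <- make_word_scheme(cfg)
  with_seed(derive_seed(cfg$seed, stream), {
    n <- if (is.null(latents)) cfg$n_proteins else nrow(latents)
    d <- cfg$latent_dim
    v <- latents %||% matrix(stats::rnorm(n * d), n, d)
    if (is.null(ids)) ids <- sprintf("P%04d", seq_len(n))

    lo <- ceiling(cfg$protein_length_range[1] / 3)
    hi <- floor(cfg$protein_length_range[2] / 3)
    bg_weight <- rep(1, sum(scheme$dim == 0L))
    if (!is.null(background_bias)) {
      bg_weight <- bg_weight * rep_len(background_bias, length(bg_weight))
    }
    seqs <- vapply(seq_len(n), function(i) {
      wt <- rep(1, nrow(scheme))
      wt[scheme$dim == 0L] <- bg_weight
      sig <- scheme$dim > 0L
      wt[sig] <- exp(signal_strength * scheme$sign[sig] * v[i, scheme$dim[sig]])
      n_words <- if (lo == hi) lo else sample(lo:hi, 1)
      paste(sample(scheme$word, n_words, replace = TRUE, prob = wt / sum(wt)),
            collapse = "")
    }, character(1))

    tibble::tibble(
      protein_id = ids,
      sequence = seqs,
      latent = lapply(seq_len(n), function(i) v[i, ])
    )
  })
}

#' Generate bioactivity records and the ground-truth interaction matrix
#'
#' A pair interacts with probability `logistic(u . v / temperature)`.
#' Interacting pairs draw potencies log-normally around 1 uM, non-interacting
#' pairs around 100 uM, so the 10 uM rule separates them up to realistic
#' tails; `label_noise_rate` of records contradict the truth. A
#' `multi_source_rate` fraction of pairs is duplicated in a second source
#' with jittered values, a share of which are binary annotations.
#'
#' @param compounds From [generate_compounds()].
#' @param proteins From [generate_proteins()].
#' @param cfg A [generator_config()].
#' @param stream Seed stream tag.
#' @return List: `records` (raw multi-source record tibble) and `truth`
#'   (tibble `compound_id`, `protein_id`, `p_interact`, `interacts`).
#' @export
generate_interactions <- function(compounds, proteins,
                                  cfg = generator_config(),
                                  stream = "interactions") {
  with_seed(derive_seed(cfg$seed, stream), {
    u <- do.call(rbind, compounds$latent)
    v <- do.call(rbind, proteins$latent)
    p <- stats::plogis((u %*% t(v)) / cfg$interaction_temperature)
    npair <- length(p)
    truth <- tibble::tibble(
      compound_id = rep(compounds$compound_id, times = nrow(proteins)),
      protein_id = rep(proteins$protein_id, each = nrow(compounds)),
      p_interact = as.numeric(p),
      interacts = stats::runif(npair) < as.numeric(p)
    )

    sample_records <- function(keys, active, source) {
      n <- nrow(keys)
      flip <- stats::runif(n) < cfg$label_noise_rate
      act <- xor(active, flip)
      binary <- stats::runif(n) < 0.15
      value_uM <- ifelse(act, stats::rlnorm(n, log(1), 1),
                         stats::rlnorm(n, log(100), 1))
      unit <- sample(c("uM", "nM"), n, replace = TRUE, prob = c(0.8, 0.2))
      tibble::tibble(
        compound_id = keys$compound_id,
        protein_id = keys$protein_id,
        assay_type = ifelse(binary, "BINARY",
                            sample(c("IC50", "Ki", "EC50"), n, replace = TRUE)),
        value = ifelse(binary, NA_real_,
                       ifelse(unit == "nM", value_uM * 1000, value_uM)),
        unit = ifelse(binary, NA_character_, unit),
        label = ifelse(binary, ifelse(act, "active", "inactive"), NA_character_),
        source = source
      )
    }

    obs <- stats::runif(npair) < cfg$observed_fraction
    keys <- truth[obs, c("compound_id", "protein_id")]
    rec1 <- sample_records(keys, truth$interacts[obs], "dbA")
    dup <- stats::runif(nrow(keys)) < cfg$multi_source_rate
    rec2 <- sample_records(keys[dup, ], truth$interacts[obs][dup], "dbB")
    list(records = dplyr::bind_rows(rec1, rec2), truth = truth)
  })
}

#' Generate a complete synthetic benchmark in memory
#'
#' @param cfg A [generator_config()].
#' @return List of class `cpi_benchmark`: `compounds`, `proteins`, `records`,
#'   `truth`, `config`.
#' @export
generate_benchmark <- function(cfg = generator_config()) {
  compounds <- generate_compounds(cfg)
  proteins <- generate_proteins(cfg)
  inter <- generate_interactions(compounds, proteins, cfg)
  structure(
    list(compounds = compounds, proteins = proteins,
         records = inter$records, truth = inter$truth, config = cfg),
    class = "cpi_benchmark"
  )
}

#' @export
print.cpi_benchmark <- function(x, ...) {
  cat(sprintf("Synthetic CPI benchmark: %d compounds x %d proteins, %d records\n",
              nrow(x$compounds), nrow(x$proteins), nrow(x$records)))
  invisible(x)
}

#' Generate external proteins for applicability analysis
#'
#' Two groups sharing the benchmark's latent interaction model: `near`
#' proteins are small perturbations of training latents with the training
#' corpus's sequence statistics (inside the training domain); `far` proteins
#' draw latents from the same prior but belong to a different "family" -
#' their sequences encode the latent only weakly and use a shifted background
#' composition - so their embeddings lie far from the training cloud and
#' carry little usable signal. Prediction quality should therefore degrade
#' with embedding distance to the training set.
#'
#' @param benchmark A [generate_benchmark()] result.
#' @param n_near,n_far Group sizes.
#' @param near_sd Latent perturbation for the near group. Default 0.05.
#' @param far_signal Signal strength of the far family's sequences. Default
#'   0.15.
#' @param far_bias_words Number of background words over-represented (8x) in
#'   the far family. Default 12.
#' @return List: `proteins` (tibble with `group` column) and `truth`/`records`
#'   for the external pairs against the benchmark compounds.
#' @export
generate_external_proteins <- function(benchmark, n_near = 15, n_far = 15,
                                       near_sd = 0.05, far_signal = 0.15,
                                       far_bias_words = 12) {
  cfg <- benchmark$config
  d <- cfg$latent_dim
  vtrain <- do.call(rbind, benchmark$proteins$latent)
  lat <- with_seed(derive_seed(cfg$seed, "external-latents"), {
    near <- vtrain[sample.int(nrow(vtrain), n_near, replace = TRUE), , drop = FALSE] +
      matrix(stats::rnorm(n_near * d, 0, near_sd), n_near, d)
    far <- matrix(stats::rnorm(n_far * d), n_far, d)
    rbind(near, far)
  })
  scheme <- make_word_scheme(cfg)
  n_bg <- sum(scheme$dim == 0L)
  bias <- with_seed(derive_seed(cfg$seed, "external-bias"), {
    b <- rep(1, n_bg)
    b[sample.int(n_bg, min(far_bias_words, n_bg))] <- 8
    b
  })
  near_prot <- generate_proteins(cfg, latents = lat[seq_len(n_near), , drop = FALSE],
                                 ids = sprintf("XN%03d", seq_len(n_near)),
                                 scheme = scheme, stream = "external-seq-near")
  far_prot <- generate_proteins(cfg, latents = lat[n_near + seq_len(n_far), , drop = FALSE],
                                ids = sprintf("XF%03d", seq_len(n_far)),
                                scheme = scheme, stream = "external-seq-far",
                                signal_strength = far_signal,
                                background_bias = bias)
  prot <- dplyr::bind_rows(near_prot, far_prot)
  prot$group <- rep(c("near", "far"), c(n_near, n_far))
  inter <- generate_interactions(benchmark$compounds, prot, cfg,
                                 stream = "external-inter")
  list(proteins = prot, records = inter$records, truth = inter$truth)
}

#' Write a benchmark to the pipeline's input file formats
#'
#' Emits the records TSV, a compounds TSV (id, molecular weight, on-bit
#' indices), a protein FASTA and a ground-truth JSON into `dir`. A round trip
#' through [read_bioactivity()], [read_compounds()] and [read_proteins()]
#' reproduces the generated tables.
#'
#' @param cfg A [generator_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of file paths plus the benchmark object.
#' @export
make_benchmark_fixture <- function(cfg = generator_config(), dir = tempfile("bench-")) {
  bench <- generate_benchmark(cfg)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    records = file.path(dir, "records.tsv"),
    compounds = file.path(dir, "compounds.tsv"),
    proteins = file.path(dir, "proteins.fasta"),
    truth = file.path(dir, "truth.json")
  )
  write_bioactivity(bench$records, paths$records)
  write_compounds(bench$compounds, paths$compounds)
  write_proteins(bench$proteins, paths$proteins)
  jsonlite::write_json(
    list(config = unclass(bench$config),
         truth = bench$truth[c("compound_id", "protein_id", "interacts")]),
    paths$truth, auto_unbox = TRUE, digits = NA
  )
  invisible(c(paths, list(benchmark = bench)))
}
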