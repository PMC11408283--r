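#' Curation configuration
#'
#' Bundles the rules used to turn raw multi-source bioactivity records into a
#' deduplicated, labeled compound-protein interaction (CPI) dataset: the 10 uM
#' activity threshold, the 100-1000 Da molecular-weight window, the 0.8
#' Tanimoto ligand-redundancy cutoff, the per-protein negative cap and the
#' train fraction.
#'
#' @param activity_threshold_uM Potency cutoff in micromolar; a pair with any
#'   IC50/Ki/EC50 at or below it is labeled positive. Default 10.
#' @param mw_min_Da,mw_max_Da Inclusive molecular-weight window in Daltons.
#'   Compounds outside it are removed before labeling. Defaults 100 and 1000.
#' @param tanimoto_cutoff Similarity above which two ligands of the same
#'   protein are considered redundant. Default 0.8.
#' @param negatives_cap_per_protein Maximum retained negatives per protein
#'   (ranked by interaction count). Default 1000.
#' @param train_fraction Fraction of pairs assigned to the training split.
#'   Default 0.8.
#' @param catalogue_sources Character vector of source tags treated as
#'   known-interaction catalogues: any record from such a source marks the
#'   pair positive regardless of potency (e.g. curated drug-target databases).
#' @param seed Integer seed controlling the random split.
#'
#' @return A list of class `cpi_curation_config`.
#' @export
curation_config <- function(activity_threshold_uM = 10,
                            mw_min_Da = 100,
                            mw_max_Da = 1000,
                            tanimoto_cutoff = 0.8,
                            negatives_cap_per_protein = 1000,
                            train_fraction = 0.8,
                            catalogue_sources = character(),
                            seed = 1L) {
  assert_that(tanimoto_cutoff > 0 && tanimoto_cutoff < 1,
              "`tanimoto_cutoff` must be in (0, 1)")
  assert_that(mw_min_Da < mw_max_Da, "`mw_min_Da` must be below `mw_max_Da`")
  assert_that(train_fraction > 0 && train_fraction < 1,
              "`train_fraction` must be in (0, 1)")
  assert_that(activity_threshold_uM > 0, "`activity_threshold_uM` must be positive")
  assert_that(negatives_cap_per_protein >= 1, "`negatives_cap_per_protein` must be >= 1")
  structure(
    list(
      activity_threshold_uM = activity_threshold_uM,
      mw_min_Da = mw_min_Da,
      mw_max_Da = mw_max_Da,
      tanimoto_cutoff = tanimoto_cutoff,
      negatives_cap_per_protein = negatives_cap_per_protein,
      train_fraction = train_fraction,
      catalogue_sources = catalogue_sources,
      seed = as.integer(seed)
    ),
    class = "cpi_curation_config"
  )
}

# unit -> multiplier to micromolar
.unit_to_uM <- c(
  "nM" = 1e-3, "nm" = 1e-3,
  "uM" = 1, "um" = 1, "µM" = 1, "µm" = 1, "microM" = 1,
  "mM" = 1e3, "mm" = 1e3
)

#' Normalize potency values to micromolar
#'
#' Accepts nM, uM (also written with a micro sign) and mM. Records with an
#' unrecognized unit are returned as `NA` with a warning; callers drop them.
#'
#' @param value Numeric potency values.
#' @param unit Character units, one per value.
#' @return Numeric vector in micromolar (`NA` where the unit is unknown).
#' @export
normalize_potency <- function(value, unit) {
  assert_that(length(value) == length(unit), "`value` and `unit` lengths differ")
  mult <- unname(.unit_to_uM[unit])
  bad <- !is.na(value) & is.na(mult)
  if (any(bad)) {
    rlang::warn(sprintf(
      "%d record(s) with unrecognized potency unit(s) [%s] rejected",
      sum(bad), paste(unique(unit[bad]), collapse = ", ")
    ))
  }
  out <- value * mult
  neg <- !is.na(out) & out < 0
  if (any(neg)) {
    rlang::warn(sprintf("%d record(s) with negative potency rejected", sum(neg)))
    out[neg] <- NA_real_
  }
  out
}

#' Tanimoto similarity between two fingerprint bit sets
#'
#' `|A intersect B| / |A union B|` over on-bit positions; defined as 0 when
#' both sets are empty.
#'
#' @param fpA,fpB Integer vectors of on-bit positions (1-based), or logical
#'   vectors of equal length.
#' @return A number in `[0, 1]`.
#' @export
tanimoto <- function(fpA, fpB) {
  if (is.logical(fpA) || is.logical(fpB)) {
    assert_that(is.logical(fpA) && is.logical(fpB) && length(fpA) == length(fpB),
                "logical fingerprints must have equal bit length")
    fpA <- which(fpA)
    fpB <- which(fpB)
  }
  a <- unique(as.integer(fpA))
  b <- unique(as.integer(fpB))
  if (length(a) == 0 && length(b) == 0) return(0)
  inter <- length(intersect(a, b))
  inter / (length(a) + length(b) - inter)
}

# Pairwise Tanimoto within a set of fingerprints via one sparse cross-product.
# Returns a dense similarity matrix; intended for per-protein groups.
tanimoto_matrix <- function(fps, nbits) {
  s <- fp_sparse_matrix(fps, nbits)
  inter <- as.matrix(Matrix::tcrossprod(s))
  sizes <- lengths(lapply(fps, unique))
  un <- outer(sizes, sizes, "+") - inter
  out <- ifelse(un == 0, 0, inter / un)
  diag(out) <- ifelse(sizes == 0, 0, 1)
  out
}

#' Filter compounds by molecular weight
#'
#' Keeps compounds with weight inside the inclusive window
#' `[mw_min_Da, mw_max_Da]` (default 100-1000 Da), focusing the dataset on
#' small molecules. Compounds with a missing weight are rejected with a
#' warning.
#'
#' @param compounds Tibble with columns `compound_id` and `mol_weight_Da`.
#' @param cfg A [curation_config()].
#' @return The retained rows of `compounds`.
#' @export
filter_by_weight <- function(compounds, cfg = curation_config()) {
  assert_that(all(c("compound_id", "mol_weight_Da") %in% names(compounds)),
              "`compounds` needs columns compound_id, mol_weight_Da")
  missing_w <- is.na(compounds$mol_weight_Da)
  if (any(missing_w)) {
    rlang::warn(sprintf("%d compound(s) without molecular weight rejected",
                        sum(missing_w)))
  }
  dplyr::filter(
    compounds,
    !is.na(.data$mol_weight_Da),
    .data$mol_weight_Da >= cfg$mw_min_Da,
    .data$mol_weight_Da <= cfg$mw_max_Da
  )
}

#' Resolve all records of one compound-protein pair into a labeled pair
#'
#' A pair is positive if any record supports activity: a potency at or below
#' the threshold (boundary inclusive), a binary "active" annotation, or any
#' record from a known-interaction catalogue source. It is negative only if
#' every interpretable record is negative. The representative potency is the
#' minimum over the pair's potency values (the most potent measurement).
#'
#' @param records Tibble of bioactivity records for a single
#'   (compound, protein) pair, with columns `compound_id`, `protein_id`,
#'   `assay_type` (IC50/Ki/EC50/BINARY), `value_uM` (micromolar, `NA` for
#'   BINARY), `binary_label` ("active"/"inactive", `NA` otherwise), `source`.
#' @param cfg A [curation_config()].
#' @return A one-row tibble (`compound_id`, `protein_id`, `label`,
#'   `representative_value_uM`, `provenance`, `conflict`) or `NULL` when no
#'   record is interpretable.
#' @export
resolve_activity <- function(records, cfg = curation_config()) {
  key <- unique(records[c("compound_id", "protein_id")])
  assert_that(nrow(key) == 1L,
              "`resolve_activity()` expects records of a single compound-protein pair")
  # accept raw records (value + unit, label) as well as normalized ones
  if (!"value_uM" %in% names(records) && all(c("value", "unit") %in% names(records))) {
    records$value_uM <- normalize_potency(records$value, records$unit)
  }
  if (!"binary_label" %in% names(records) && "label" %in% names(records)) {
    records$binary_label <- records$label
  }
  out <- resolve_pairs(records, cfg)
  if (nrow(out) == 0) NULL else out
}

# Vectorized resolution across many pairs (grouped summarise).
resolve_pairs <- function(records, cfg) {
  needed <- c("compound_id", "protein_id", "assay_type", "value_uM",
              "binary_label", "source")
  assert_that(all(needed %in% names(records)),
              paste("records need columns:", paste(needed, collapse = ", ")))

  rec <- records |>
    dplyr::mutate(
      pos_evidence = (!is.na(.data$value_uM) &
                        .data$value_uM <= cfg$activity_threshold_uM) |
        (!is.na(.data$binary_label) & .data$binary_label == "active") |
        (.data$source %in% cfg$catalogue_sources),
      neg_evidence = (!is.na(.data$value_uM) &
                        .data$value_uM > cfg$activity_threshold_uM) |
        (!is.na(.data$binary_label) & .data$binary_label == "inactive"),
      interpretable = .data$pos_evidence | .data$neg_evidence
    ) |>
    dplyr::filter(.data$interpretable)

  if (nrow(rec) == 0) {
    return(tibble::tibble(
      compound_id = character(), protein_id = character(),
      label = character(), representative_value_uM = double(),
      provenance = character(), conflict = logical()
    ))
  }

  rec |>
    dplyr::group_by(.data$compound_id, .data$protein_id) |>
    dplyr::summarise(
      label = dplyr::if_else(any(.data$pos_evidence), "positive", "negative"),
      representative_value_uM = ifelse(
        all(is.na(.data$value_uM)), NA_real_,
        min(.data$value_uM, na.rm = TRUE)
      ),
      provenance = paste(sort(unique(.data$source)), collapse = ";"),
      conflict = any(.data$pos_evidence) && any(.data$neg_evidence),
      .groups = "drop"
    )
}

#' Remove redundant ligands of a protein (hidden ligand bias)
#'
#' Within groups of mutually similar compounds acting on the same protein
#' (Tanimoto above the cutoff, Morgan-style bit fingerprints), only the
#' compound with the largest interaction count survives. Grouping is greedy
#' leader clustering: compounds are visited in decreasing interaction count
#' (ties broken by compound id); a compound similar to an already retained
#' leader is discarded, otherwise it becomes a leader.
#'
#' @param compounds_with_counts Tibble with columns `compound_id`,
#'   `interaction_count` and a `fingerprint` list-column of on-bit indices.
#' @param cfg A [curation_config()].
#' @param nbits Fingerprint length in bits.
#' @return The retained rows, in visit order.
#' @export
deduplicate_ligand_bias <- function(compounds_with_counts,
                                    cfg = curation_config(),
                                    nbits = 2048) {
  tbl <- compounds_with_counts
  assert_that(all(c("compound_id", "interaction_count", "fingerprint") %in% names(tbl)),
              "need columns compound_id, interaction_count, fingerprint")
  if (nrow(tbl) <= 1) return(tbl)
  tbl <- dplyr::arrange(tbl, dplyr::desc(.data$interaction_count), .data$compound_id)
  sim <- tanimoto_matrix(tbl$fingerprint, nbits)
  leaders <- integer(0)
  for (i in seq_len(nrow(tbl))) {
    if (length(leaders) == 0 || all(sim[i, leaders] <= cfg$tanimoto_cutoff)) {
      leaders <- c(leaders, i)
    }
  }
  tbl[leaders, , drop = FALSE]
}

#' Cap negatives per protein
#'
#' Retains at most `negatives_cap_per_protein` negative ligands of one
#' protein: candidates are ranked by interaction count (descending, ties by
#' compound id) and accepted only if their Tanimoto similarity to every
#' previously accepted survivor is strictly below the cutoff.
#'
#' @inheritParams deduplicate_ligand_bias
#' @return The retained rows, in acceptance order.
#' @export
cap_negatives_per_protein <- function(compounds_with_counts,
                                      cfg = curation_config(),
                                      nbits = 2048) {
  tbl <- compounds_with_counts
  assert_that(all(c("compound_id", "interaction_count", "fingerprint") %in% names(tbl)),
              "need columns compound_id, interaction_count, fingerprint")
  if (nrow(tbl) == 0) return(tbl)
  tbl <- dplyr::arrange(tbl, dplyr::desc(.data$interaction_count), .data$compound_id)
  sim <- tanimoto_matrix(tbl$fingerprint, nbits)
  accepted <- integer(0)
  for (i in seq_len(nrow(tbl))) {
    if (length(accepted) >= cfg$negatives_cap_per_protein) break
    if (length(accepted) == 0 || all(sim[i, accepted] < cfg$tanimoto_cutoff)) {
      accepted <- c(accepted, i)
    }
  }
  tbl[accepted, , drop = FALSE]
}

#' Curate a raw multi-source bioactivity table into a labeled CPI dataset
#'
#' Applies, in order: potency unit normalization to micromolar,
#' molecular-weight filtering, per-pair label resolution (any-active rule,
#' minimum representative potency), per-protein ligand deduplication of
#' positives and negatives separately, and per-protein negative capping.
#'
#' @param records Tibble of raw records with columns `compound_id`,
#'   `protein_id`, `assay_type`, `value`, `unit`, `label`, `source`
#'   (`value`/`unit` `NA` for BINARY records; `label` `NA` otherwise).
#' @param compounds Tibble with `compound_id`, `mol_weight_Da` and a
#'   `fingerprint` list-column of on-bit indices.
#' @param cfg A [curation_config()].
#' @param nbits Fingerprint length in bits.
#' @return An object of class `cpi_curation`: a list with `pairs` (tibble:
#'   `compound_id`, `protein_id`, `label`, `representative_value_uM`,
#'   `provenance`), `report` (counts removed per rule) and `config`.
#' @export
curate_dataset <- function(records, compounds, cfg = curation_config(),
                           nbits = 2048) {
  needed <- c("compound_id", "protein_id", "assay_type", "value", "unit",
              "label", "source")
  assert_that(all(needed %in% names(records)),
              paste("records need columns:", paste(needed, collapse = ", ")))
  report <- list(n_records = nrow(records))

  rec <- records |>
    dplyr::mutate(
      value_uM = normalize_potency(.data$value, .data$unit),
      binary_label = .data$label
    )
  # potency assays whose value did not normalize are uninterpretable
  rejected_unit <- rec$assay_type != "BINARY" & !is.na(rec$value) & is.na(rec$value_uM)
  report$rejected_bad_unit <- sum(rejected_unit)
  rec <- rec[!rejected_unit, , drop = FALSE]

  kept_compounds <- filter_by_weight(compounds, cfg)
  report$compounds_removed_mw <- nrow(compounds) - nrow(kept_compounds)
  n_before <- nrow(rec)
  rec <- dplyr::semi_join(rec, kept_compounds, by = "compound_id")
  report$records_removed_mw <- n_before - nrow(rec)

  pairs <- resolve_pairs(rec, cfg)
  report$resolved_pairs <- nrow(pairs)
  report$conflicting_pairs <- sum(pairs$conflict)
  if (report$conflicting_pairs > 0) {
    rlang::inform(sprintf(
      "%d pair(s) had conflicting active/inactive evidence; resolved by the any-active rule",
      report$conflicting_pairs
    ))
  }

  # interaction count: resolved pairs a compound participates in, any protein,
  # any label, within this working dataset
  counts <- dplyr::count(pairs, .data$compound_id, name = "interaction_count")
  fps <- kept_compounds[c("compound_id", "fingerprint")]
  pairs_fp <- pairs |>
    dplyr::left_join(counts, by = "compound_id") |>
    dplyr::left_join(fps, by = "compound_id")

  dedup_one <- function(grp) {
    deduplicate_ligand_bias(grp, cfg, nbits)
  }
  deduped <- pairs_fp |>
    dplyr::group_by(.data$protein_id, .data$label) |>
    dplyr::group_modify(~ dedup_one(.x)) |>
    dplyr::ungroup()
  report$dedup_removed <- nrow(pairs_fp) - nrow(deduped)

  neg <- dplyr::filter(deduped, .data$label == "negative")
  pos <- dplyr::filter(deduped, .data$label == "positive")
  capped <- neg |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::group_modify(~ cap_negatives_per_protein(.x, cfg, nbits)) |>
    dplyr::ungroup()
  report$cap_removed <- nrow(neg) - nrow(capped)

  out <- dplyr::bind_rows(pos, capped) |>
    dplyr::arrange(.data$protein_id, .data$compound_id) |>
    dplyr::select("compound_id", "protein_id", "label",
                  "representative_value_uM", "provenance")
  report$final_pairs <- nrow(out)
  report$final_positive <- sum(out$label == "positive")
  report$final_negative <- sum(out$label == "negative")

  structure(list(pairs = out, report = report, config = cfg),
            class = "cpi_curation")
}

#' @export
print.cpi_curation <- function(x, ...) {
  r <- x$report
  cat("Curated CPI dataset\n")
  cat(sprintf("  records in:            %d\n", r$n_records))
  cat(sprintf("  bad-unit rejected:     %d\n", r$rejected_bad_unit))
  cat(sprintf("  MW-filtered records:   %d\n", r$records_removed_mw))
  cat(sprintf("  resolved pairs:        %d (%d conflicting)\n",
              r$resolved_pairs, r$conflicting_pairs))
  cat(sprintf("  ligand-dedup removed:  %d\n", r$dedup_removed))
  cat(sprintf("  negative-cap removed:  %d\n", r$cap_removed))
  cat(sprintf("  final: %d pairs (%d positive / %d negative)\n",
              r$final_pairs, r$final_positive, r$final_negative))
  invisible(x)
}

#' @export
glance.cpi_curation <- function(x, ...) {
  tibble::as_tibble(x$report)
}

#' Percentage of overlapping pairs relative to the smaller dataset
#'
#' @param n_a,n_b Dataset sizes.
#' @param n_overlap Size of the intersection.
#' @return `100 * n_overlap / min(n_a, n_b)`, rounded to 2 decimals; `NA` when
#'   either dataset is empty.
#' @export
overlap_percentage <- function(n_a, n_b, n_overlap) {
  ifelse(n_a == 0 | n_b == 0, NA_real_,
         round(100 * n_overlap / pmin(n_a, n_b), 2))
}

#' Cross-source overlap statistics
#'
#' For every pair of named datasets of CPI keys, reports the sizes, the
#' intersection count, and the overlap percentage relative to the smaller
#' dataset (rounded to two decimals).
#'
#' @param datasets Named list (>= 2 entries) of character vectors of CPI keys
#'   (e.g. `"compound|protein"`).
#' @return Tibble with columns `dataset_a`, `dataset_b`, `n_a`, `n_b`,
#'   `overlap`, `pct_of_smaller`. Diagonal rows carry the totals.
#' @export
dataset_overlap_stats <- function(datasets) {
  assert_that(is.list(datasets) && length(datasets) >= 2 &&
                !is.null(names(datasets)) && all(nzchar(names(datasets))),
              "`datasets` must be a named list of at least two key vectors")
  sets <- lapply(datasets, unique)
  nm <- names(sets)
  grid <- tidyr::expand_grid(a = nm, b = nm) |>
    dplyr::filter(match(.data$a, nm) <= match(.data$b, nm))
  purrr::pmap(grid, function(a, b) {
    ov <- if (a == b) length(sets[[a]]) else length(intersect(sets[[a]], sets[[b]]))
    tibble::tibble(
      dataset_a = a, dataset_b = b,
      n_a = length(sets[[a]]), n_b = length(sets[[b]]),
      overlap = ov,
      pct_of_smaller = overlap_percentage(length(sets[[a]]), length(sets[[b]]), ov)
    )
  }) |>
    purrr::list_rbind()
}

#' Random train/test split of a curated dataset
#'
#' Splits labeled pairs into disjoint train and test sets with
#' `|train| = round-half-up(train_fraction * n)`, deterministically under the
#' configuration seed.
#'
#' @param pairs Tibble of labeled pairs.
#' @param cfg A [curation_config()]; uses `train_fraction` and `seed`.
#' @return A list with tibbles `train` and `test`.
#' @export
split_dataset <- function(pairs, cfg = curation_config()) {
  n <- nrow(pairs)
  assert_that(n >= 5, "need at least 5 pairs to split")
  n_train <- floor(cfg$train_fraction * n + 0.5)
  idx <- with_seed(derive_seed(cfg$seed, "split"), sample.int(n, n_train))
  list(train = pairs[sort(idx), , drop = FALSE],
       test = pairs[setdiff(seq_len(n), idx), , drop = FALSE])
}
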