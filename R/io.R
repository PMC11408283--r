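#' Read and write bioactivity record tables
#'
#' Records are TSV (or CSV) with header columns `compound_id`, `protein_id`,
#' `assay_type` (IC50/Ki/EC50/BINARY), `value`, `unit`, `label`
#' (active/inactive for BINARY rows), `source`.
#'
#' @param path File path.
#' @return Tibble of records.
#' @export
read_bioactivity <- function(path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  rec <- readr::read_delim(
    path, delim = delim, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      compound_id = readr::col_character(),
      protein_id = readr::col_character(),
      assay_type = readr::col_character(),
      value = readr::col_double(),
      unit = readr::col_character(),
      label = readr::col_character(),
      source = readr::col_character()
    )
  )
  needed <- c("compound_id", "protein_id", "assay_type", "value", "unit",
              "label", "source")
  assert_that(all(needed %in% names(rec)),
              paste("bioactivity file needs columns:", paste(needed, collapse = ", ")))
  rec
}

#' @rdname read_bioactivity
#' @param records Tibble of records.
#' @export
write_bioactivity <- function(records, path) {
  readr::write_tsv(records, path, progress = FALSE)
  invisible(path)
}

#' Read and write compound tables
#'
#' Compounds are TSV with `compound_id`, `mol_weight_Da` and either a
#' `fingerprint` column of semicolon-separated on-bit indices or a `smiles`
#' column (fingerprints are then computed with [morgan_fingerprint()]).
#'
#' @param path File path.
#' @param nbits Fingerprint length used when computing from SMILES.
#' @return Tibble with a `fingerprint` list-column.
#' @export
read_compounds <- function(path, nbits = 2048) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  assert_that(all(c("compound_id", "mol_weight_Da") %in% names(tbl)),
              "compound file needs columns compound_id, mol_weight_Da")
  if ("fingerprint" %in% names(tbl)) {
    tbl$fingerprint <- lapply(
      stringr::str_split(as.character(tbl$fingerprint), ";"),
      function(x) sort(as.integer(x[nzchar(x)]))
    )
  } else if ("smiles" %in% names(tbl)) {
    tbl$fingerprint <- morgan_fingerprint(tbl$smiles, nbits = nbits)
  } else {
    rlang::abort("compound file needs a `fingerprint` or `smiles` column")
  }
  tbl
}

#' @rdname read_compounds
#' @param compounds Tibble with a `fingerprint` list-column.
#' @export
write_compounds <- function(compounds, path) {
  out <- compounds |>
    dplyr::mutate(
      fingerprint = purrr::map_chr(.data$fingerprint, paste, collapse = ";")
    ) |>
    dplyr::select(dplyr::any_of(c("compound_id", "mol_weight_Da", "smiles",
                                  "fingerprint", "twin_of")))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read and write protein sequences (FASTA)
#'
#' @param path File path.
#' @return Tibble with `protein_id` and `sequence`.
#' @export
read_proteins <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  tibble::tibble(
    protein_id = sub("\\s.*$", "", names(seqs)),
    sequence = unname(as.character(seqs))
  )
}

#' @rdname read_proteins
#' @param proteins Tibble with `protein_id` and `sequence`.
#' @export
write_proteins <- function(proteins, path) {
  x <- Biostrings::AAStringSet(proteins$sequence)
  names(x) <- proteins$protein_id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read and write curated pair tables
#'
#' @param path File path.
#' @return Tibble with `compound_id`, `protein_id`, `label`,
#'   `representative_value_uM`, `provenance`.
#' @export
read_pairs <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    compound_id = readr::col_character(),
                    protein_id = readr::col_character(),
                    label = readr::col_character(),
                    representative_value_uM = readr::col_double(),
                    provenance = readr::col_character()
                  ))
}

#' @rdname read_pairs
#' @param pairs Tibble of curated pairs.
#' @export
write_pairs <- function(pairs, path) {
  readr::write_tsv(pairs, path, progress = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' Every pipeline command emits a JSON manifest recording the package
#' version, the stage, input file checksums, per-stage record counts and a
#' timestamp, so runs can be audited and reproduced.
#'
#' @param dir Output directory.
#' @param stage Stage name.
#' @param counts Named list of record counts.
#' @param inputs Character vector of input file paths (checksummed if they
#'   exist).
#' @param extra Optional named list merged into the manifest.
#' @return Invisibly, the manifest path.
#' @export
write_manifest <- function(dir, stage, counts = list(), inputs = character(),
                           extra = list()) {
  existing <- inputs[file.exists(inputs)]
  manifest <- c(list(
    tool = "cpipred",
    version = as.character(utils::packageVersion("cpipred")),
    stage = stage,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    input_checksums = as.list(tools::md5sum(existing)),
    counts = counts
  ), extra)
  path <- file.path(dir, paste0("manifest-", stage, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
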