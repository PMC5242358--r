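#' Read and write the pipeline's delimited-text formats
#'
#' All on-disk artefacts are UTF-8 tab-separated text with a header row:
#' feature tables carry drug-group columns `g1..gG` and a `disease` label
#' column; signature tables carry `disease` plus `g1..gG` 0/1 columns; raw
#' prescriptions are `id` plus a semicolon-separated `drugs` field; drug-group
#' mappings are two columns `drug`, `group` with one row per (drug, group)
#' membership.
#'
#' @param path File path.
#' @name rx_io
NULL

#' @rdname rx_io
#' @export
read_features <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"disease" %in% names(out)) {
    warn("feature file has no `disease` column; labels are absent.")
  }
  out
}

#' @rdname rx_io
#' @param data Feature tibble (`g1..gG`, optionally `disease`).
#' @export
write_features <- function(data, path) {
  readr::write_tsv(data, path)
  invisible(path)
}

#' @rdname rx_io
#' @export
read_signature_table <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE)
  if (!"disease" %in% names(out)) {
    abort("signature table must have a `disease` column.")
  }
  m <- feature_matrix(out)
  if (!all(m %in% c(0, 1))) {
    abort("signature table entries must be 0/1.")
  }
  structure(out, class = c("rx_signature_table", class(out)))
}

#' @rdname rx_io
#' @param table Signature table tibble.
#' @export
write_signature_table <- function(table, path) {
  readr::write_tsv(tibble::as_tibble(table), path)
  invisible(path)
}

#' @rdname rx_io
#' @export
read_prescriptions <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    id = readr::col_character(), drugs = readr::col_character()
  ))
  if (!all(c("id", "drugs") %in% names(out))) {
    abort("prescription file must have columns `id` and `drugs`.")
  }
  out
}

#' @rdname rx_io
#' @export
read_drug_group_mapping <- function(path) {
  out <- readr::read_tsv(path, col_types = readr::cols(
    drug = readr::col_character(), group = readr::col_integer()
  ))
  validate_mapping(out)
}

#' Write a generated dataset to a directory
#'
#' Writes `features.tsv` (counts + label), `signatures.tsv` (ground truth)
#' and `config.yaml` (the full simulation configuration, including the seed,
#' as an audit trail).
#'
#' @param dataset An `rx_dataset` from [generate_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "rx_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_features(dataset$features, file.path(dir, "features.tsv"))
  write_signature_table(dataset$signatures, file.path(dir, "signatures.tsv"))
  write_sim_config(dataset$config, file.path(dir, "config.yaml"))
  invisible(dir)
}

#' @rdname write_dataset
#' @param config An [sim_config()].
#' @param path YAML file path.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "rx_sim_config"))
  lst <- unclass(config)
  lst$overlap_pairs <- lapply(lst$overlap_pairs, as.integer)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_sim_config <- function(path) {
  lst <- yaml::read_yaml(path)
  do.call(sim_config, lst)
}
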