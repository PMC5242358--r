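#' Encode one prescription as a drug-group count vector
#'
#' Turns a prescription (a multiset of drug identifiers) into counts over `G`
#' drug groups. Each drug increments every group it is mapped to by 1; a drug
#' belonging to two groups increments both, and two drugs of one group yield
#' a cell value of 2. Counts are unbounded non-negative integers — the rule
#' generalizes past 2 without capping.
#'
#' @param drugs Character vector of drug identifiers (repeats allowed).
#' @param mapping A drug-group mapping: tibble with columns `drug` (character)
#'   and `group` (integer in `1..G`); a drug mapped to several groups appears
#'   on several rows. See [read_drug_group_mapping()].
#' @param n_groups Total group count `G`; defaults to `max(mapping$group)`.
#' @param unknown What to do with a drug absent from the mapping: `"error"`
#'   (default — silent dropping would bias class signals) or `"skip"`, which
#'   drops it with a warning.
#'
#' @return Integer count vector of length `n_groups`.
#' @export
#'
#' @examples
#' m <- tibble::tibble(drug = c("a", "a", "b"), group = c(3L, 7L, 5L))
#' encode_prescription(c("a"), m, n_groups = 8)
#' encode_prescription(c("b", "b"), m, n_groups = 8)
encode_prescription <- function(drugs, mapping, n_groups = NULL,
                                unknown = c("error", "skip")) {
  unknown <- match.arg(unknown)
  mapping <- validate_mapping(mapping)
  if (is.null(n_groups)) n_groups <- max(mapping$group)
  n_groups <- as.integer(n_groups)
  if (any(mapping$group > n_groups)) {
    abort("`mapping` refers to group indices beyond `n_groups`.")
  }
  if (length(drugs) == 0L || all(is.na(drugs))) {
    abort("a prescription must contain at least one drug.")
  }
  drugs <- as.character(drugs)

  missing <- setdiff(unique(drugs), mapping$drug)
  if (length(missing) > 0L) {
    if (unknown == "error") {
      abort(paste0("unknown drug identifier(s): ",
                   paste(missing, collapse = ", ")))
    }
    warn(paste0("skipping unknown drug identifier(s): ",
                paste(missing, collapse = ", ")))
    drugs <- drugs[drugs %in% mapping$drug]
    if (length(drugs) == 0L) {
      return(integer(n_groups))
    }
  }

  # every (drug occurrence, group) incidence contributes 1
  hits <- unlist(lapply(drugs, function(d) mapping$group[mapping$drug == d]),
                 use.names = FALSE)
  x <- tabulate(hits, nbins = n_groups)
  as.integer(x)
}

#' Build the prescriptions-by-drug-groups feature table
#'
#' Encodes a set of prescriptions row by row with [encode_prescription()],
#' producing the n-by-G count table the classifiers consume (rows =
#' prescriptions, columns = drug groups in index order).
#'
#' @param prescriptions Tibble with columns `id` and `drugs`, where `drugs` is
#'   either a list-column of character vectors or a single
#'   semicolon-separated string per row. See [read_prescriptions()].
#' @param mapping Drug-group mapping as in [encode_prescription()].
#' @param labels Optional vector of disease classes, aligned 1:1 with
#'   `prescriptions`; stored as a `disease` column.
#' @param n_groups Total group count `G`; defaults to `max(mapping$group)`.
#' @inheritParams encode_prescription
#'
#' @return Tibble with columns `id`, `g1..gG`, and `disease` when `labels`
#'   is supplied.
#' @export
build_feature_matrix <- function(prescriptions, mapping, labels = NULL,
                                 n_groups = NULL,
                                 unknown = c("error", "skip")) {
  unknown <- match.arg(unknown)
  if (!is.data.frame(prescriptions) ||
      !all(c("id", "drugs") %in% names(prescriptions))) {
    abort("`prescriptions` must have columns `id` and `drugs`.")
  }
  mapping <- validate_mapping(mapping)
  if (is.null(n_groups)) n_groups <- max(mapping$group)

  drug_lists <- prescriptions$drugs
  if (!is.list(drug_lists)) {
    drug_lists <- strsplit(as.character(drug_lists), ";", fixed = TRUE)
    drug_lists <- lapply(drug_lists, trimws)
  }

  if (!is.null(labels) && length(labels) != nrow(prescriptions)) {
    abort("`labels` must align 1:1 with `prescriptions`.")
  }

  rows <- vapply(drug_lists, encode_prescription, integer(n_groups),
                 mapping = mapping, n_groups = n_groups, unknown = unknown)
  m <- t(matrix(rows, nrow = n_groups))
  colnames(m) <- group_cols(n_groups)

  out <- dplyr::bind_cols(
    tibble::tibble(id = prescriptions$id),
    tibble::as_tibble(m)
  )
  if (!is.null(labels)) out$disease <- as.integer(labels)
  out
}

validate_mapping <- function(mapping) {
  if (!is.data.frame(mapping) || !all(c("drug", "group") %in% names(mapping))) {
    abort("`mapping` must be a data frame with columns `drug` and `group`.")
  }
  if (nrow(mapping) == 0L) abort("`mapping` must contain at least one drug.")
  mapping$drug <- as.character(mapping$drug)
  mapping$group <- as.integer(mapping$group)
  if (any(is.na(mapping$group)) || any(mapping$group < 1L)) {
    abort("`mapping$group` indices must be positive integers.")
  }
  mapping
}
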