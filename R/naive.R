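#' Shared drug groups between a prescription and a disease signature
#'
#' Number of drug groups present in both the prescription and the disease
#' signature: the intersection of supports. Counts are not weighted — a group
#' holding two drugs still contributes 1.
#'
#' @param x Non-negative count vector (one prescription).
#' @param signature_row Binary 0/1 vector of the same length.
#'
#' @return Non-negative integer.
#' @export
#'
#' @examples
#' shared_group_count(c(1, 0, 2, 0), c(1, 1, 1, 0))
shared_group_count <- function(x, signature_row) {
  if (length(x) != length(signature_row)) {
    abort("`x` and `signature_row` must have equal length.")
  }
  sum(x > 0 & signature_row == 1)
}

#' Normalized shared-group score
#'
#' Normalizes the shared-group count `a` between prescription `i` and disease
#' `j` by the geometric mean of the prescription's group count `b` and the
#' disease's group count `c`:
#'
#' \deqn{m = a / \sqrt{b \cdot c}}
#'
#' which is the cosine similarity of the two binary supports and lies in
#' `[0, 1]`; diseases with large drug repertoires are not favoured merely for
#' their size.
#'
#' @param a Shared group count, `0 <= a <= min(b, c)`.
#' @param b Number of distinct drug groups of the prescription (support
#'   size — counts of 2 do not raise it). Must be positive.
#' @param c Number of drug groups of the disease. Must be positive.
#'
#' @return Score in `[0, 1]`.
#' @export
#'
#' @examples
#' naive_score(2, 4, 9)  # 2 / sqrt(36) = 1/3
naive_score <- function(a, b, c) {
  if (any(b <= 0) || any(c <= 0)) {
    abort("`b` and `c` must be positive group counts.")
  }
  if (any(a < 0) || any(a > pmin(b, c))) {
    abort("`a` must satisfy 0 <= a <= min(b, c).")
  }
  a / sqrt(b * c)
}

#' Classify prescriptions by nearest disease signature
#'
#' The baseline ("naive") classifier: each prescription is scored against
#' every disease row of the signature table with [naive_score()] and tagged
#' with the disease attaining the largest normalized score. Scores depend
#' only on supports, so scaling counts changes nothing.
#'
#' Ties — including the degenerate all-zero-score case of a prescription
#' sharing no group with any disease — go to the lowest class index and are
#' flagged in the output (and summarised in a warning), so tie events stay
#' auditable.
#'
#' @param data Feature tibble with drug-group columns `g1..gG` (extra columns
#'   such as `disease` are ignored for scoring).
#' @param signature_table `K x G` binary signature table
#'   ([generate_signature_table()] or [read_signature_table()]).
#'
#' @return Tibble with one row per prescription: `.pred` (class 1..K),
#'   `.score` (the winning normalized score) and `.tie` (logical).
#' @export
#'
#' @examples
#' cfg <- sim_config(n_prescriptions = 20, n_classes = 3, n_groups = 12,
#'                   overlap_pairs = list(), noise_rate = 0, seed = 2)
#' ds <- generate_dataset(cfg)
#' naive_classify(ds$features, ds$signatures)
naive_classify <- function(data, signature_table) {
  X <- feature_matrix(data)
  S <- signature_matrix(signature_table)
  if (ncol(X) != ncol(S)) {
    abort("feature columns and signature table columns do not match.")
  }

  b <- rowSums(X > 0)          # distinct groups per prescription
  if (any(b == 0)) {
    abort("every prescription must contain at least one drug group.")
  }
  cc <- rowSums(S)             # groups per disease
  if (any(cc == 0)) {
    abort("every disease signature must contain at least one drug group.")
  }

  A <- (X > 0) %*% t(S)        # n x K shared-group counts
  M <- A / sqrt(outer(b, cc))  # normalized scores

  pred <- max.col(M, ties.method = "first")
  best <- M[cbind(seq_len(nrow(M)), pred)]
  tie <- rowSums(abs(M - best) < 1e-12) > 1L
  if (any(tie)) {
    warn(sprintf("%d prescription(s) had tied top scores; lowest class index used.",
                 sum(tie)))
  }

  tibble::tibble(.pred = as.integer(pred), .score = as.numeric(best),
                 .tie = tie)
}

#' Naive-baseline model specification
#'
#' Wraps a ground-truth signature table as a classifier specification so the
#' baseline can run through the same [cross_validate()] harness as the
#' learned classifiers. The baseline does not learn from training folds — its
#' signature table is fixed knowledge.
#'
#' @param signature_table `K x G` binary signature table.
#' @return An object of class `rx_naive_spec`.
#' @export
naive_spec <- function(signature_table) {
  structure(list(signature_table = signature_table, name = "naive"),
            class = "rx_naive_spec")
}

#' @export
print.rx_naive_spec <- function(x, ...) {
  cat("<rx_naive_spec> normalized shared-drug-group baseline\n")
  invisible(x)
}
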