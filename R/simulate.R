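#' Configure a synthetic prescription simulation
#'
#' Describes a synthetic population of outpatient prescriptions: `K` disease
#' classes, `G` drug groups, one binary drug-group signature per disease, and
#' per-prescription noise. The defaults emulate the structure of an outpatient
#' prescription registry in which ten diseases of interest coexist with a
#' heterogeneous "other diseases" class (the last class index): that class is
#' simulated as a union of several sub-signatures, and by default shares part
#' of its drug repertoire with class 1 (an asthma-like respiratory class),
#' which is where real prescription data concentrates its confusions.
#'
#' @param n_prescriptions Number of prescriptions to simulate.
#' @param n_classes Number of disease classes `K`; class `K` is the
#'   heterogeneous "other diseases" class.
#' @param n_groups Number of drug groups `G` (feature dimension).
#' @param signature_size Either a length-2 integer range from which each
#'   class's signature size is drawn, or a length-`K` integer vector of exact
#'   sizes. For the "other" class the size applies to each sub-signature.
#' @param overlap_pairs List of integer triples `c(class_a, class_b, n_shared)`
#'   forcing `n_shared` drug groups to be common to both signatures.
#' @param noise_rate Probability that a prescription carries unrelated
#'   ("noise") drug groups in addition to its disease signature. Outpatient
#'   prescriptions commonly include one or more non-related medications, so
#'   the default is high.
#' @param extra_noise_count Length-2 integer range: how many off-signature
#'   groups a noisy prescription receives.
#' @param duplicate_prob Probability that a signature group holds two drugs of
#'   the prescription (cell value 2 instead of 1).
#' @param class_prevalence Length-`K` probability vector (sums to 1). Default:
#'   the "other" class takes 25% and the remaining mass is uniform.
#' @param other_subsignatures Number of disjoint sub-signatures pooled into
#'   the "other" class; each simulated "other" prescription draws one of them.
#'   Set to 1 for a homogeneous last class.
#' @param seed Integer seed; the whole dataset is drawn from one stream.
#'
#' @return An object of class `rx_sim_config` (a validated list).
#' @export
#'
#' @examples
#' cfg <- sim_config(n_prescriptions = 200, seed = 7)
#' cfg$n_classes
sim_config <- function(n_prescriptions = 1412,
                       n_classes = 11,
                       n_groups = 60,
                       signature_size = c(2L, 6L),
                       overlap_pairs = list(c(1L, 11L, 2L)),
                       noise_rate = 0.7,
                       extra_noise_count = c(1L, 2L),
                       duplicate_prob = 0.2,
                       class_prevalence = NULL,
                       other_subsignatures = 3,
                       seed = 1L) {
  if (!is.numeric(n_prescriptions) || n_prescriptions < 1) {
    abort("`n_prescriptions` must be a positive integer.")
  }
  if (!is.numeric(n_classes) || n_classes < 1) {
    abort("`n_classes` must be a positive integer.")
  }
  if (!is.numeric(n_groups) || n_groups < 1) {
    abort("`n_groups` must be a positive integer.")
  }
  K <- as.integer(n_classes)
  G <- as.integer(n_groups)

  signature_size <- as.integer(signature_size)
  if (!length(signature_size) %in% c(2L, K)) {
    abort("`signature_size` must be a length-2 range or a length-K vector.")
  }
  if (any(signature_size < 1L) || any(signature_size > G)) {
    abort("signature sizes must lie in [1, n_groups].")
  }
  if (length(signature_size) == 2L && signature_size[1] > signature_size[2]) {
    abort("`signature_size` range must be non-decreasing.")
  }

  overlap_pairs <- lapply(overlap_pairs, as.integer)
  for (p in overlap_pairs) {
    if (length(p) != 3L) {
      abort("each element of `overlap_pairs` must be c(class_a, class_b, n_shared).")
    }
    if (any(p[1:2] < 1L) || any(p[1:2] > K) || p[1] == p[2]) {
      abort("overlap pair classes must be distinct indices in 1..K.")
    }
    if (p[3] < 1L) abort("`n_shared` must be at least 1.")
  }
  # drop pairs referring to classes that do not exist at this K (the default
  # pair targets class 11 and would be meaningless for a small toy K)
  overlap_pairs <- Filter(function(p) p[1] <= K && p[2] <= K, overlap_pairs)

  check_scalar_prob(noise_rate, "noise_rate")
  check_scalar_prob(duplicate_prob, "duplicate_prob")
  extra_noise_count <- as.integer(extra_noise_count)
  if (length(extra_noise_count) == 1L) {
    extra_noise_count <- rep(extra_noise_count, 2L)
  }
  if (length(extra_noise_count) != 2L || any(extra_noise_count < 0L) ||
      extra_noise_count[1] > extra_noise_count[2]) {
    abort("`extra_noise_count` must be a non-decreasing length-2 range of non-negative integers.")
  }

  if (is.null(class_prevalence)) {
    class_prevalence <- if (K == 1L) {
      1
    } else {
      c(rep(0.75 / (K - 1), K - 1), 0.25)
    }
  }
  if (length(class_prevalence) != K || any(class_prevalence < 0)) {
    abort("`class_prevalence` must be a non-negative length-K vector.")
  }
  if (abs(sum(class_prevalence) - 1) > 1e-9) {
    abort("`class_prevalence` must sum to 1 (tolerance 1e-9).")
  }

  other_subsignatures <- as.integer(other_subsignatures)
  if (other_subsignatures < 1L) abort("`other_subsignatures` must be >= 1.")

  structure(
    list(
      n_prescriptions = as.integer(n_prescriptions),
      n_classes = K,
      n_groups = G,
      signature_size = signature_size,
      overlap_pairs = overlap_pairs,
      noise_rate = noise_rate,
      extra_noise_count = extra_noise_count,
      duplicate_prob = duplicate_prob,
      class_prevalence = as.numeric(class_prevalence),
      other_subsignatures = other_subsignatures,
      seed = as.integer(seed)
    ),
    class = "rx_sim_config"
  )
}

#' @export
print.rx_sim_config <- function(x, ...) {
  cat("<rx_sim_config>\n")
  cat(sprintf("  n = %d prescriptions, K = %d classes, G = %d drug groups\n",
              x$n_prescriptions, x$n_classes, x$n_groups))
  cat(sprintf("  noise_rate = %.2f, duplicate_prob = %.2f, seed = %d\n",
              x$noise_rate, x$duplicate_prob, x$seed))
  invisible(x)
}

# Resolve per-class signature sizes from a range or an explicit vector.
signature_sizes <- function(config) {
  K <- config$n_classes
  s <- config$signature_size
  if (length(s) == K && K != 2L) return(s)
  if (length(s) == K && K == 2L && s[1] == s[2]) return(s)
  if (length(s) == 2L) {
    rng <- seq(s[1], s[2])
    return(if (length(rng) == 1L) rep(rng, K)
           else sample(rng, K, replace = TRUE))
  }
  s
}

#' Generate a disease-signature table
#'
#' Builds the `K x G` binary table linking each disease class to its
#' characteristic drug groups. Groups are assigned by partitioning a seeded
#' random permutation of `1..G`; overlapping groups requested through
#' `overlap_pairs` are carved out first, so the constraints are met exactly
#' and the remaining assignments are disjoint. The "other" class (index `K`)
#' may be a union of disjoint sub-signatures (see [sim_config()]); the
#' sub-signatures are kept in the `"subsignatures"` attribute.
#'
#' @param config An [sim_config()] object.
#' @param seed Seed for the assignment; defaults to `config$seed`.
#'
#' @return A tibble with columns `disease` (1..K) and `g1..gG` (0/1), of class
#'   `rx_signature_table`.
#' @export
#'
#' @examples
#' tab <- generate_signature_table(sim_config(n_classes = 3, n_groups = 10,
#'                                            overlap_pairs = list(),
#'                                            other_subsignatures = 1))
#' rowSums(tab[-1])
generate_signature_table <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "rx_sim_config"))
  K <- config$n_classes
  G <- config$n_groups

  with_rng_seed(seed, {
    sizes <- signature_sizes(config)
    n_sub <- config$other_subsignatures

    # one slot set per ordinary class; the last class expands to sub-signatures
    slots <- c(seq_len(K - 1), rep(K, n_sub))
    slot_sizes <- c(sizes[seq_len(max(K - 1, 0))], rep(sizes[K], n_sub))
    if (K == 1L) {
      slots <- rep(1L, n_sub)
      slot_sizes <- rep(sizes[1], n_sub)
    }

    shared_per_slot <- vector("list", length(slot_sizes))
    pool <- sample.int(G)
    # Draw k groups, preferring the untouched pool so signatures stay
    # disjoint where possible; once the pool is exhausted, incidental reuse
    # of already-assigned groups (never within the same signature) is
    # allowed — real drug groups are shared across diseases too. Only a
    # request that cannot be met at all is a configuration error.
    take <- function(k, exclude = integer(0), strict = FALSE) {
      if (strict && k > length(pool)) {
        abort(paste0(
          "infeasible overlap request: the demanded shared groups exceed ",
          "the available drug groups (n_groups = ", G, ")."
        ))
      }
      from_pool <- min(k, length(pool))
      out <- if (from_pool > 0) pool[seq_len(from_pool)] else integer(0)
      if (from_pool > 0) pool <<- pool[-seq_len(from_pool)]
      short <- k - from_pool
      if (short > 0) {
        avail <- setdiff(seq_len(G), c(out, exclude))
        if (length(avail) < short) {
          abort(paste0(
            "infeasible signature configuration: a signature of the ",
            "requested size does not fit into n_groups = ", G, "."
          ))
        }
        out <- c(out, avail[sample.int(length(avail), short)])
      }
      out
    }

    # first slot belonging to a class (class K -> its first sub-signature)
    slot_of_class <- function(cl) which(slots == cl)[1]

    for (p in config$overlap_pairs) {
      a <- slot_of_class(p[1]); b <- slot_of_class(p[2]); s <- p[3]
      if (s > min(slot_sizes[a], slot_sizes[b])) {
        abort("overlap request exceeds a signature size.")
      }
      g <- take(s, strict = TRUE)
      shared_per_slot[[a]] <- c(shared_per_slot[[a]], g)
      shared_per_slot[[b]] <- c(shared_per_slot[[b]], g)
    }

    groups <- vector("list", length(slot_sizes))
    for (i in seq_along(slot_sizes)) {
      have <- shared_per_slot[[i]] %||% integer(0)
      need <- slot_sizes[i] - length(have)
      if (need < 0) abort("overlap requests exceed a signature size.")
      groups[[i]] <- sort(c(have, take(need, exclude = have)))
    }

    mat <- matrix(0L, nrow = K, ncol = G)
    for (i in seq_along(groups)) {
      mat[slots[i], groups[[i]]] <- 1L
    }
    colnames(mat) <- group_cols(G)

    subs <- groups[slots == K]
    out <- tibble::as_tibble(mat)
    out <- dplyr::bind_cols(tibble::tibble(disease = seq_len(K)), out)
    structure(out,
              class = c("rx_signature_table", class(out)),
              subsignatures = subs,
              config = config)
  })
}

signature_matrix <- function(table) {
  m <- feature_matrix(table)
  storage.mode(m) <- "integer"
  m
}

#' Sample one prescription's drug-group count vector
#'
#' Draws a single prescription for a disease class: each signature group of
#' the class receives count 1, or 2 with probability `duplicate_prob` (two
#' drugs of the prescription falling in the same group); with probability
#' `noise_rate` the prescription additionally carries unrelated medications,
#' i.e. a few off-signature groups with count 1. Uses the current RNG stream.
#'
#' @param class_label Disease class in `1..K`.
#' @param table A signature table from [generate_signature_table()].
#' @param config The [sim_config()] the table was built from.
#'
#' @return Integer count vector of length `G`.
#' @export
sample_prescription <- function(class_label, table, config) {
  K <- config$n_classes
  G <- config$n_groups
  if (!is.numeric(class_label) || length(class_label) != 1L ||
      class_label < 1 || class_label > K) {
    abort("`class_label` must be a single class index in 1..K.")
  }
  class_label <- as.integer(class_label)

  subs <- attr(table, "subsignatures")
  if (class_label == K && length(subs) > 1L) {
    sig <- subs[[sample.int(length(subs), 1L)]]
  } else {
    sig <- which(signature_matrix(table)[class_label, ] == 1L)
  }

  x <- integer(G)
  dup <- stats::rbinom(length(sig), 1L, config$duplicate_prob)
  x[sig] <- 1L + dup

  if (config$noise_rate > 0 && stats::runif(1) < config$noise_rate) {
    rng <- config$extra_noise_count
    k <- if (rng[1] == rng[2]) rng[1] else sample(seq(rng[1], rng[2]), 1L)
    off <- setdiff(seq_len(G), sig)
    k <- min(k, length(off))
    if (k > 0) {
      picked <- off[sample.int(length(off), k)]
      x[picked] <- 1L
    }
  }
  x
}

#' Generate a labelled synthetic prescription dataset
#'
#' Draws class labels from `class_prevalence` and one count vector per
#' prescription via [sample_prescription()]. The entire dataset comes from a
#' single RNG stream seeded once with `config$seed`, so identical configs give
#' bit-identical datasets.
#'
#' @param config An [sim_config()] object.
#'
#' @return An `rx_dataset`: a list with `features` (tibble `g1..gG` +
#'   `disease`), `signatures` (the ground-truth [generate_signature_table()]
#'   output) and `config`.
#' @export
#'
#' @examples
#' ds <- generate_dataset(sim_config(n_prescriptions = 50, seed = 1))
#' dplyr::count(ds$features, disease)
generate_dataset <- function(config) {
  stopifnot(inherits(config, "rx_sim_config"))
  n <- config$n_prescriptions
  if (n < 1L) abort("`n_prescriptions` must be positive.")

  with_rng_seed(config$seed, {
    table <- generate_signature_table(config, seed = NULL)
    labels <- sample.int(config$n_classes, n, replace = TRUE,
                         prob = config$class_prevalence)
    rows <- t(vapply(labels, sample_prescription,
                     integer(config$n_groups),
                     table = table, config = config))
    colnames(rows) <- group_cols(config$n_groups)
    features <- tibble::as_tibble(rows)
    features$disease <- labels

    structure(
      list(features = features, signatures = table, config = config),
      class = "rx_dataset"
    )
  })
}

#' @export
print.rx_dataset <- function(x, ...) {
  cat(sprintf("<rx_dataset> %d prescriptions x %d drug groups, %d classes\n",
              nrow(x$features), x$config$n_groups, x$config$n_classes))
  invisible(x)
}
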