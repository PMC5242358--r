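# Small shared fixtures, generated in code.

# Separable toy world: disjoint signatures, no noise.
toy_separable <- function(n = 120, K = 4, G = 16, seed = 101) {
  sim_config(
    n_prescriptions = n, n_classes = K, n_groups = G,
    signature_size = c(2, 3), overlap_pairs = list(),
    noise_rate = 0, duplicate_prob = 0,
    class_prevalence = rep(1 / K, K),
    other_subsignatures = 1, seed = seed
  )
}

# Noisy world with an asthma-like class sharing groups with the "other" class.
toy_noisy <- function(n = 200, seed = 202) {
  sim_config(
    n_prescriptions = n, n_classes = 5, n_groups = 25,
    signature_size = c(2, 4), overlap_pairs = list(c(1, 5, 1)),
    noise_rate = 0.5, duplicate_prob = 0.2,
    other_subsignatures = 2, seed = seed
  )
}

# Independent brute-force re-implementation of the normalized
# shared-group classifier, via explicit set enumeration.
brute_naive_classify <- function(X, S) {
  n <- nrow(X); K <- nrow(S)
  out <- integer(n)
  for (i in seq_len(n)) {
    sup <- which(X[i, ] > 0)
    scores <- numeric(K)
    for (j in seq_len(K)) {
      sig <- which(S[j, ] == 1)
      a <- length(intersect(sup, sig))
      scores[j] <- a / sqrt(length(sup) * length(sig))
    }
    out[i] <- which.max(scores)  # first maximum = lowest class index
  }
  out
}

# Independent brute-force one-vs-rest metric counter.
brute_metrics <- function(truth, pred, K) {
  res <- matrix(NA_real_, K, 3)
  for (cl in seq_len(K)) {
    tp <- sum(truth == cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    fp <- sum(truth != cl & pred == cl)
    tn <- sum(truth != cl & pred != cl)
    res[cl, 1] <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
    res[cl, 2] <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
    res[cl, 3] <- if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_
  }
  colnames(res) <- c("sensitivity", "specificity", "precision")
  res
}

# Independent unweighted majority vote with the package's documented
# tie rule collapsed for equal weights: lowest class index wins ties.
brute_majority <- function(row, K) {
  counts <- tabulate(row, nbins = K)
  which.max(counts)
}
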