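test_that("signature tables honour sizes, disjointness and overlap requests", {
  # two classes, forced disjoint
  cfg <- sim_config(n_prescriptions = 10, n_classes = 2, n_groups = 4,
                    signature_size = c(2L, 2L), overlap_pairs = list(),
                    other_subsignatures = 1, seed = 1)
  tab <- generate_signature_table(cfg)
  S <- as.matrix(tab[-1])
  expect_equal(unname(rowSums(S)), c(2, 2))
  expect_equal(sum(S[1, ] & S[2, ]), 0)

  # forced single shared column at G = 3
  cfg2 <- sim_config(n_prescriptions = 10, n_classes = 2, n_groups = 3,
                     signature_size = c(2L, 2L),
                     overlap_pairs = list(c(1, 2, 1)),
                     other_subsignatures = 1, seed = 1)
  S2 <- as.matrix(generate_signature_table(cfg2)[-1])
  expect_equal(sum(S2[1, ] & S2[2, ]), 1)
  expect_equal(unname(rowSums(S2)), c(2, 2))

  # overlap honoured exactly at realistic scale
  cfg3 <- sim_config(seed = 9)
  S3 <- as.matrix(generate_signature_table(cfg3)[-1])
  shared_1_11 <- sum(S3[1, ] & S3[11, ])
  expect_gte(shared_1_11, 2)
})

test_that("signature table generation is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 7)
  expect_identical(generate_signature_table(cfg),
                   generate_signature_table(cfg))
})

test_that("an impossible signature request raises a configuration error", {
  expect_error(
    sim_config(n_prescriptions = 5, n_classes = 2, n_groups = 3,
               signature_size = c(4L, 4L), other_subsignatures = 1),
    "signature sizes"
  )
  # overlap demand alone exceeding G
  cfg <- sim_config(n_prescriptions = 5, n_classes = 4, n_groups = 5,
                    signature_size = c(3L, 3L),
                    overlap_pairs = list(c(1, 2, 3), c(3, 4, 3)),
                    other_subsignatures = 2, seed = 1)
  expect_error(generate_signature_table(cfg), "infeasible")
})

test_that("config validation rejects malformed prevalence and rates", {
  expect_error(sim_config(class_prevalence = rep(0.1, 11)), "sum to 1")
  expect_error(sim_config(noise_rate = 1.5), "probability")
  expect_error(sim_config(n_prescriptions = 0), "positive")
})

test_that("sampled prescriptions follow the signature, duplicate and noise rules", {
  cfg <- toy_separable(seed = 5)
  tab <- generate_signature_table(cfg)
  S <- as.matrix(tab[-1])

  # no noise, no duplicates: support contained in the class signature
  set.seed(11)
  for (cl in 1:4) {
    x <- sample_prescription(cl, tab, cfg)
    expect_true(all(which(x > 0) %in% which(S[cl, ] == 1)))
    expect_true(all(x %in% c(0L, 1L)))
  }

  # duplicate_prob = 1: every signature cell holds exactly 2
  cfg_dup <- toy_separable(seed = 5)
  cfg_dup$duplicate_prob <- 1
  set.seed(12)
  x <- sample_prescription(2, tab, cfg_dup)
  expect_true(all(x[S[2, ] == 1] == 2L))
  expect_true(all(x[S[2, ] == 0] == 0L))

  # noise_rate = 1 with exactly one extra group: one off-signature positive
  cfg_noise <- toy_separable(seed = 5)
  cfg_noise$noise_rate <- 1
  cfg_noise$extra_noise_count <- c(1L, 1L)
  set.seed(13)
  x <- sample_prescription(3, tab, cfg_noise)
  expect_equal(sum(x > 0 & S[3, ] == 0), 1)

  expect_error(sample_prescription(99, tab, cfg), "class index")
})

test_that("generated datasets are reproducible and respect prevalence", {
  cfg <- sim_config(n_prescriptions = 1000,
                    class_prevalence = rep(1 / 11, 11), seed = 21)
  ds1 <- generate_dataset(cfg)
  ds2 <- generate_dataset(cfg)
  expect_identical(ds1$features, ds2$features)
  expect_identical(ds1$signatures, ds2$signatures)

  # every prescription carries at least one drug group
  expect_true(all(rowSums(ds1$features[paste0("g", 1:60)]) > 0))

  # each class count within +-4 multinomial standard errors of n/K
  counts <- table(factor(ds1$features$disease, levels = 1:11))
  expected <- 1000 / 11
  se <- sqrt(1000 * (1 / 11) * (10 / 11))
  expect_true(all(abs(counts - expected) <= 4 * se))

  # degenerate prevalence concentrates all labels
  cfg1 <- sim_config(n_prescriptions = 40,
                     class_prevalence = c(1, rep(0, 10)), seed = 3)
  expect_true(all(generate_dataset(cfg1)$features$disease == 1))
})

test_that("empirical class frequencies converge to the configured prevalence", {
  cfg <- sim_config(n_prescriptions = 10000, seed = 31)
  ds <- generate_dataset(cfg)
  counts <- as.vector(table(factor(ds$features$disease, levels = 1:11)))
  gof <- stats::chisq.test(counts, p = cfg$class_prevalence)
  expect_gt(gof$p.value, 0.001)
})

test_that("the 'other' class draws from its sub-signatures", {
  cfg <- sim_config(n_prescriptions = 300, n_classes = 3, n_groups = 30,
                    signature_size = c(3L, 3L, 3L), overlap_pairs = list(),
                    noise_rate = 0, duplicate_prob = 0,
                    class_prevalence = c(0.2, 0.2, 0.6),
                    other_subsignatures = 3, seed = 17)
  ds <- generate_dataset(cfg)
  subs <- attr(ds$signatures, "subsignatures")
  expect_length(subs, 3)
  expect_true(all(lengths(subs) == 3))
  # union row equals the union of the sub-signatures
  S <- as.matrix(ds$signatures[-1])
  expect_setequal(which(S[3, ] == 1), sort(unique(unlist(subs))))
  # every 'other' prescription matches exactly one sub-signature support
  other <- ds$features[ds$features$disease == 3, paste0("g", 1:30)]
  hits <- apply(as.matrix(other), 1, function(x) {
    sup <- which(x > 0)
    sum(vapply(subs, function(s) setequal(sup, s), TRUE))
  })
  expect_true(all(hits == 1))
})
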