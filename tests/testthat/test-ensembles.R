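random_prediction_matrix <- function(n, N, K) {
  matrix(sample.int(K, n * N, replace = TRUE), n, N)
}

test_that("learned weights follow the closed form beta^errors", {
  set.seed(601)
  for (rep in 1:200) {
    n <- sample(5:40, 1); N <- sample(2:8, 1); K <- sample(2:11, 1)
    P <- random_prediction_matrix(n, N, K)
    y <- sample.int(K, n, replace = TRUE)
    beta <- runif(1, 0.05, 1)
    w <- learn_weights(P, y, beta)
    errors <- colSums(P != y)
    expect_equal(w$errors, as.integer(errors))
    expect_equal(w$weight, beta ^ errors, tolerance = 1e-12)
    expect_true(all(w$weight > 0))
    # anti-monotone: more errors, smaller weight (strict for beta < 1)
    if (beta < 1) {
      ord <- order(errors)
      expect_true(all(diff(w$weight[ord]) <= 0))
      distinct <- diff(errors[ord]) > 0
      expect_true(all(diff(w$weight[ord])[distinct] < 0))
    }
  }
})

test_that("beta = 1 gives unit weights and an error-free classifier keeps weight 1", {
  P <- cbind(c(1, 2, 2), c(1, 1, 1))
  w <- learn_weights(P, c(1, 2, 2), beta = 1)
  expect_equal(w$weight, c(1, 1))

  # one error at beta = 0.5 halves exactly one weight
  w2 <- learn_weights(cbind(c(1, 2), c(1, 1)), c(1, 2), beta = 0.5)
  expect_equal(w2$weight, c(1, 0.5))
  expect_equal(w2$errors, c(0L, 1L))

  expect_error(learn_weights(P, c(1, 2, 2), beta = 0), "\\(0, 1\\]")
  expect_error(learn_weights(P, c(1, 2, 2), beta = 1.2), "\\(0, 1\\]")
})

test_that("votes maximize summed weights with the documented tie rule", {
  expect_equal(as.integer(vote(c(1, 1, 2))), 1L)
  expect_equal(as.integer(vote(c(2, 1, 1), weights = c(3, 1, 1))), 2L)
  # unanimous vote wins under any weights
  expect_equal(as.integer(vote(c(4, 4, 4), weights = c(0.1, 5, 2))), 4L)
  # tie between classes: heaviest single supporter wins
  expect_equal(
    as.integer(suppressMessages(vote(c(1, 2), weights = c(2, 2)))), 1L)
  expect_equal(
    as.integer(suppressMessages(
      vote(c(1, 2, 2), weights = c(2, 1.5, 0.5), n_classes = 2))), 1L)
  expect_error(vote(matrix(integer(0), 1, 0)), "empty")
})

test_that("weighted voting with beta = 1 is exactly unweighted majority vote", {
  set.seed(602)
  for (rep in 1:1000) {
    n <- sample(1:50, 1); N <- sample(1:8, 1); K <- sample(2:11, 1)
    P <- random_prediction_matrix(n, N, K)
    y <- sample.int(K, n, replace = TRUE)
    w <- learn_weights(P, y, beta = 1)
    got <- as.integer(vote(P, weights = w, n_classes = K, quiet = TRUE))
    want <- apply(P, 1, brute_majority, K = K)
    expect_identical(got, want)
  }
})

test_that("meta-datasets have n rows, N+1 prediction columns and equal folds", {
  ds <- generate_dataset(toy_separable(n = 10, K = 2, G = 10, seed = 71))
  specs <- base_specs(seed = 5)
  meta <- build_meta_dataset(ds$features, specs, J = 5, seed = 8)
  expect_equal(nrow(meta), 10L)
  expect_equal(ncol(meta), 6L + 2L)  # fold + 6 predictions + disease
  expect_equal(unname(table(meta$fold)), rep(2L, 5), ignore_attr = TRUE)

  # same seed, same fold assignment
  meta2 <- build_meta_dataset(ds$features, specs, J = 5, seed = 8)
  expect_identical(meta$fold, meta2$fold)

  expect_error(build_meta_dataset(ds$features, specs, J = 11), "exceed")
  expect_error(build_meta_dataset(ds$features, specs, J = 1), "at least 2")
})

test_that("no meta-dataset row is predicted by a model trained on it", {
  # memorization audit: 1-NN on unique rows with signal-free labels would
  # recover its own label if a fold ever saw its own rows at training time
  set.seed(73)
  G <- 8; n <- 60
  X <- matrix(sample(0:5, n * G, replace = TRUE), n, G)
  X[, 1] <- seq_len(n)  # force unique rows
  colnames(X) <- paste0("g", seq_len(G))
  data <- tibble::as_tibble(X)
  data$disease <- rep(1:3, each = 20)[sample.int(n)]
  meta <- suppressWarnings(
    build_meta_dataset(data, list(knn = make_spec("knn")), J = 6, seed = 2)
  )
  # labels are pure noise, so out-of-fold 1-NN accuracy must sit near chance
  expect_lt(mean(meta$knn == data$disease), 0.8)
})

test_that("perfect base learners make meta columns equal truth and stacking exact", {
  ds <- generate_dataset(toy_separable(n = 80, seed = 74))
  specs <- list(knn = make_spec("knn"))
  meta <- build_meta_dataset(ds$features, specs, J = 4, seed = 3)
  expect_equal(meta$knn, ds$features$disease)

  # N = 1 meta-feature equal to truth -> perfect stacked predictions
  new_preds <- tibble::tibble(knn = c(1L, 2L, 3L, 4L))
  expect_equal(stack_fit_predict(meta, new_preds), c(1L, 2L, 3L, 4L))
})

test_that("the 3-NN meta-learner predicts the label of identical meta rows", {
  meta <- tibble::tibble(
    fold = c(1L, 1L, 1L, 2L, 2L, 2L),
    a = c(2L, 2L, 2L, 1L, 1L, 1L),
    b = c(2L, 2L, 2L, 3L, 3L, 3L),
    disease = c(2L, 2L, 2L, 1L, 1L, 1L)
  )
  got <- stack_fit_predict(meta, tibble::tibble(a = 2L, b = 2L),
                           n_classes = 3)
  expect_equal(got, 2L)
})

test_that("beta tuning returns the plain-voting accuracy on a singleton grid", {
  ds <- generate_dataset(toy_separable(n = 80, seed = 75))
  specs <- list(knn = make_spec("knn"), dt = make_spec("decision_tree"))
  res <- tune_beta(ds$features, specs, grid = 1.0, folds = 4, seed = 6,
                   inner_folds = 3)
  expect_equal(res$best_beta, 1.0)
  expect_equal(nrow(res$table), 1L)
  ev <- cross_validate(ds$features,
                       ensemble_spec(specs, "voting"), folds = 4, seed = 6)
  expect_equal(res$table$accuracy, ev$accuracy)
})

test_that("on separable data all betas tie and the largest wins, grid order aside", {
  ds <- generate_dataset(toy_separable(n = 80, seed = 76))
  specs <- list(knn = make_spec("knn"), dt = make_spec("decision_tree"))
  grid <- c(0.4, 0.7, 1.0)
  res <- tune_beta(ds$features, specs, grid = grid, folds = 4, seed = 6,
                   inner_folds = 3)
  expect_equal(res$best_beta, 1.0)
  expect_true(all(res$table$accuracy == 100))
  res_perm <- tune_beta(ds$features, specs, grid = rev(grid), folds = 4,
                        seed = 6, inner_folds = 3)
  expect_equal(res_perm$best_beta, res$best_beta)

  expect_error(tune_beta(ds$features, specs, grid = numeric(0)), "non-empty")
  expect_error(tune_beta(ds$features, specs, grid = c(0.5, 1.5)), "\\(0, 1\\]")
  expect_error(tune_beta(ds$features, specs, grid = 0.5, folds = 1),
               "at least 2")
})
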