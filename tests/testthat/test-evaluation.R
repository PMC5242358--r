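test_that("confusion matrices count exactly", {
  cm <- confusion_matrix(c(1, 1, 2), c(1, 2, 2), n_classes = 2)
  expect_equal(unclass(cm), matrix(c(1L, 0L, 1L, 1L), 2, 2),
               ignore_attr = TRUE)
  expect_equal(sum(cm), 3)

  # perfect predictions give a diagonal matrix of class counts
  y <- rep(1:3, times = c(4, 2, 5))
  cmd <- confusion_matrix(y, y, n_classes = 3)
  expect_equal(diag(cmd), setNames(c(4L, 2L, 5L), 1:3))
  expect_equal(sum(cmd) - sum(diag(cmd)), 0)

  # empty input gives an all-zero matrix
  cm0 <- confusion_matrix(integer(0), integer(0), n_classes = 4)
  expect_true(all(cm0 == 0L))
  expect_equal(dim(cm0), c(4L, 4L))

  expect_error(confusion_matrix(c(1, 5), c(1, 1), n_classes = 3), "1..n")
  expect_error(confusion_matrix(1:3, 1:2), "equal length")
})

test_that("per-class metrics match hand counts and flag undefined ratios", {
  cm <- confusion_matrix(c(1, 1, 2), c(1, 2, 2), n_classes = 2)
  m <- per_class_metrics(cm)
  expect_equal(m$sensitivity, c(50, 100))
  expect_equal(m$precision, c(100, 50))

  # a class never predicted and never present: all ratios undefined -> NA
  cm3 <- confusion_matrix(c(1, 2), c(1, 2), n_classes = 3)
  m3 <- per_class_metrics(cm3)
  expect_true(is.na(m3$sensitivity[3]))
  expect_true(is.na(m3$precision[3]))
  expect_false(is.na(m3$specificity[3]))

  # a class present but never predicted: precision NA, sensitivity 0
  cm4 <- confusion_matrix(c(1, 2, 2), c(1, 1, 1), n_classes = 2)
  m4 <- per_class_metrics(cm4)
  expect_true(is.na(m4$precision[2]))
  expect_equal(m4$sensitivity[2], 0)
})

test_that("metrics agree exactly with a brute-force one-vs-rest counter", {
  set.seed(801)
  for (rep in 1:1000) {
    K <- sample(2:11, 1)
    n <- sample(1:60, 1)
    truth <- sample.int(K, n, replace = TRUE)
    pred <- sample.int(K, n, replace = TRUE)
    cm <- confusion_matrix(truth, pred, n_classes = K)
    got <- per_class_metrics(cm)
    want <- brute_metrics(truth, pred, K)
    expect_equal(got$sensitivity, unname(want[, "sensitivity"]))
    expect_equal(got$specificity, unname(want[, "specificity"]))
    expect_equal(got$precision, unname(want[, "precision"]))
    # micro-accuracy identity
    expect_equal(100 * sum(diag(cm)) / n, 100 * mean(truth == pred))
  }
})

test_that("stratified folds cover all samples and balance classes", {
  y <- rep(1:4, times = c(40, 30, 20, 10))
  id <- make_folds(y, folds = 10, seed = 3)
  expect_equal(sort(unique(id)), 1:10)
  expect_equal(length(id), length(y))
  # each fold holds its share of each sufficiently supported class
  for (cl in 1:4) {
    per_fold <- table(id[y == cl])
    expect_lte(max(per_fold) - min(per_fold), 1)
  }
  expect_warning(make_folds(rep(1:2, c(5, 30)), folds = 10, seed = 1),
                 "fewer than")
  expect_error(make_folds(1:20, folds = 1), "at least 2")
})

test_that("cross-validation pools fold confusions and is seed-reproducible", {
  ds <- generate_dataset(toy_separable())
  ev <- cross_validate(ds$features, make_spec("knn"), folds = 5, seed = 4)
  expect_s3_class(ev, "rx_eval")
  expect_equal(ev$accuracy, 100)
  expect_equal(sum(ev$confusion), nrow(ds$features))

  # pooled matrix equals the sum of per-fold matrices
  y <- ds$features$disease
  pred <- integer(length(y))
  per_fold <- matrix(0L, 4, 4)
  for (f in 1:5) {
    test <- ev$fold_id == f
    fitted <- fit(make_spec("knn"), ds$features[!test, ])
    p <- predict(fitted, ds$features[test, ])
    per_fold <- per_fold + unclass(confusion_matrix(y[test], p, 4))
  }
  expect_equal(unclass(ev$confusion), per_fold, ignore_attr = TRUE)

  ev2 <- cross_validate(ds$features, make_spec("knn"), folds = 5, seed = 4)
  expect_identical(glance(ev), glance(ev2))
  expect_identical(ev$fold_id, ev2$fold_id)
})

test_that("the naive baseline runs through the same harness", {
  ds <- generate_dataset(toy_separable())
  ev <- cross_validate(ds$features, naive_spec(ds$signatures),
                       folds = 5, seed = 4)
  expect_equal(ev$method, "naive")
  expect_equal(ev$accuracy, 100)
})

test_that("tidiers and plots expose the report in standard shapes", {
  ds <- generate_dataset(toy_noisy(n = 100))
  ev <- suppressWarnings(
    cross_validate(ds$features, make_spec("decision_tree"),
                   folds = 5, seed = 2)
  )
  td <- tidy(ev)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("method", "class", "support", "sensitivity",
                     "specificity", "precision"))
  gl <- glance(ev)
  expect_equal(nrow(gl), 1L)
  expect_true(all(gl$accuracy >= 0 & gl$accuracy <= 100))

  cm_tidy <- tidy(ev$confusion)
  expect_equal(sum(cm_tidy$n), 100)

  p <- autoplot(ev)
  expect_s3_class(p, "ggplot")
  p2 <- plot_method_comparison(list(ev))
  expect_s3_class(p2, "ggplot")
})
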