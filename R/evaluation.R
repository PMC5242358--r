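#' Confusion matrix of true versus predicted disease classes
#'
#' @param truth,estimate Integer class labels in `1..n_classes`, equal length.
#' @param n_classes Number of classes `K`; defaults to the largest label seen.
#'
#' @return A `K x K` integer matrix of class `rx_confusion`; entry `(t, p)`
#'   counts samples of true class `t` predicted as `p`, so the diagonal holds
#'   the correctly classified samples and row sums are the class frequencies.
#' @export
#'
#' @examples
#' confusion_matrix(c(1, 1, 2), c(1, 2, 2), n_classes = 2)
confusion_matrix <- function(truth, estimate, n_classes = NULL) {
  if (length(truth) != length(estimate)) {
    abort("`truth` and `estimate` must have equal length.")
  }
  truth <- as.integer(truth)
  estimate <- as.integer(estimate)
  if (is.null(n_classes)) n_classes <- max(truth, estimate, 1L)
  n_classes <- as.integer(n_classes)
  if (length(truth) > 0 &&
      (min(truth, estimate) < 1L || max(truth, estimate) > n_classes)) {
    abort("labels must lie in 1..n_classes.")
  }
  cm <- matrix(0L, n_classes, n_classes,
               dimnames = list(true = seq_len(n_classes),
                               predicted = seq_len(n_classes)))
  if (length(truth) > 0) {
    tab <- table(factor(truth, levels = seq_len(n_classes)),
                 factor(estimate, levels = seq_len(n_classes)))
    cm[] <- as.integer(tab)
  }
  structure(cm, class = c("rx_confusion", "matrix", "array"))
}

#' Per-class one-vs-rest classification metrics
#'
#' For each disease class `c`, treating `c` as positive and all other classes
#' as negative: sensitivity `100 * TP / (TP + FN)`, specificity
#' `100 * TN / (TN + FP)`, precision `100 * TP / (TP + FP)`. A metric whose
#' denominator is zero (e.g. precision of a never-predicted class) is
#' reported as `NA`, never as 0.
#'
#' @param cm An [confusion_matrix()].
#' @return Tibble with columns `class`, `support`, `sensitivity`,
#'   `specificity`, `precision` (percent).
#' @export
per_class_metrics <- function(cm) {
  stopifnot(inherits(cm, "rx_confusion") ||
              (is.matrix(cm) && nrow(cm) == ncol(cm)))
  K <- nrow(cm)
  n <- sum(cm)
  tp <- unname(diag(cm))
  fn <- unname(rowSums(cm)) - tp
  fp <- unname(colSums(cm)) - tp
  tn <- n - tp - fn - fp

  pct <- function(num, den) ifelse(den > 0, 100 * num / den, NA_real_)
  tibble::tibble(
    class = seq_len(K),
    support = as.integer(rowSums(cm)),
    sensitivity = pct(tp, tp + fn),
    specificity = pct(tn, tn + fp),
    precision = pct(tp, tp + fp)
  )
}

# Stratified fold assignment: within each class, shuffle then deal round-robin
# so every fold sees every class wherever the support allows it.
make_folds <- function(y, folds, seed = NULL) {
  y <- as.integer(y)
  if (folds < 2L) abort("`folds` must be at least 2.")
  if (length(y) < folds) abort("need at least as many samples as folds.")
  with_rng_seed(seed, {
    id <- integer(length(y))
    offset <- 0L
    for (cl in sort(unique(y))) {
      idx <- which(y == cl)
      if (length(idx) < folds) {
        warn(sprintf("class %d has %d member(s), fewer than %d folds; some folds will lack it.",
                     cl, length(idx), folds))
      }
      idx <- idx[sample.int(length(idx))]
      # rotate the starting fold across classes to balance fold sizes
      id[idx] <- ((seq_along(idx) - 1L + offset) %% folds) + 1L
      offset <- (offset + length(idx)) %% folds
    }
    id
  })
}

new_rx_eval <- function(truth, pred, n_classes, method, folds, seed,
                        fold_id = NULL, extras = list()) {
  cm <- confusion_matrix(truth, pred, n_classes)
  metrics <- per_class_metrics(cm)
  structure(
    c(list(
      method = method,
      confusion = cm,
      metrics = metrics,
      accuracy = if (sum(cm) > 0) 100 * sum(diag(cm)) / sum(cm) else NA_real_,
      macro_sensitivity = mean(metrics$sensitivity, na.rm = TRUE),
      macro_specificity = mean(metrics$specificity, na.rm = TRUE),
      macro_precision = mean(metrics$precision, na.rm = TRUE),
      n = length(truth),
      folds = folds,
      seed = seed,
      fold_id = fold_id
    ), extras),
    class = "rx_eval"
  )
}

#' @export
print.rx_eval <- function(x, ...) {
  cat(sprintf("<rx_eval: %s> %d-fold CV on n = %d\n", x$method, x$folds, x$n))
  cat(sprintf("  accuracy %.1f%% | macro sensitivity %.1f%% | macro precision %.1f%%\n",
              x$accuracy, x$macro_sensitivity, x$macro_precision))
  invisible(x)
}

#' Cross-validated evaluation of a classifier or ensemble
#'
#' Runs stratified k-fold cross-validation: each fold serves once as test set
#' for a model trained on the remaining folds, out-of-fold predictions are
#' pooled into a single confusion matrix, and per-class one-vs-rest metrics
#' are computed from that pooled matrix (rather than averaged per fold).
#'
#' @param data Feature tibble with `g1..gG` columns and a `disease` label.
#' @param model What to evaluate: an [make_spec()] base-classifier spec, an
#'   [naive_spec()] baseline, or an [ensemble_spec()].
#' @param folds Number of folds (default 10).
#' @param seed Seed controlling the fold assignment (and, through the spec
#'   seeds, any stochastic fitting).
#' @param ... Passed on to method-specific machinery.
#'
#' @return An `rx_eval` object: pooled confusion matrix, per-class
#'   sensitivity/specificity/precision (percent), overall accuracy
#'   (`100 * trace / n`), macro averages, and the fold assignment.
#' @export
#'
#' @examples
#' ds <- generate_dataset(sim_config(n_prescriptions = 120, n_classes = 3,
#'                                   n_groups = 12, overlap_pairs = list(),
#'                                   noise_rate = 0, seed = 5))
#' ev <- cross_validate(ds$features, make_spec("knn"), folds = 4, seed = 1)
#' glance(ev)
cross_validate <- function(data, model, folds = 10, seed = 1L, ...) {
  UseMethod("cross_validate", model)
}

#' @export
cross_validate.rx_spec <- function(data, model, folds = 10, seed = 1L, ...) {
  y <- as.integer(data$disease)
  K <- max(y)
  fold_id <- make_folds(y, folds, seed)
  pred <- integer(length(y))
  for (f in seq_len(folds)) {
    test <- fold_id == f
    fitted <- fit(model, data[!test, , drop = FALSE])
    pred[test] <- predict(fitted, data[test, , drop = FALSE])
  }
  new_rx_eval(y, pred, K, model$name, folds, seed, fold_id)
}

#' @export
cross_validate.rx_naive_spec <- function(data, model, folds = 10, seed = 1L,
                                         ...) {
  y <- as.integer(data$disease)
  K <- max(nrow(model$signature_table), max(y))
  fold_id <- make_folds(y, folds, seed)
  # the baseline uses fixed signature knowledge, not the training folds;
  # fold structure is kept so reports stay comparable
  res <- naive_classify(data, model$signature_table)
  new_rx_eval(y, res$.pred, K, "naive", folds, seed, fold_id,
              extras = list(ties = sum(res$.tie)))
}

#' @method tidy rx_eval
#' @export
tidy.rx_eval <- function(x, ...) {
  dplyr::mutate(x$metrics, method = x$method, .before = 1)
}

#' @method glance rx_eval
#' @export
glance.rx_eval <- function(x, ...) {
  tibble::tibble(
    method = x$method,
    accuracy = x$accuracy,
    macro_sensitivity = x$macro_sensitivity,
    macro_specificity = x$macro_specificity,
    macro_precision = x$macro_precision,
    folds = x$folds,
    n = x$n
  )
}

#' @method tidy rx_confusion
#' @export
tidy.rx_confusion <- function(x, ...) {
  df <- as.data.frame(as.table(unclass(x)), stringsAsFactors = FALSE)
  names(df) <- c("true", "predicted", "n")
  tibble::as_tibble(lapply(df, function(col) {
    if (is.character(col)) as.integer(col) else col
  }))
}

#' Confusion-matrix heatmap for an evaluation report
#'
#' @param object An `rx_eval` from [cross_validate()].
#' @param ... Unused.
#' @return A ggplot object: true class by predicted class, tiles shaded by
#'   count, counts printed in the cells.
#' @method autoplot rx_eval
#' @export
autoplot.rx_eval <- function(object, ...) {
  df <- tidy(object$confusion)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$predicted),
                                   y = factor(.data$true,
                                              levels = rev(sort(unique(.data$true)))),
                                   fill = .data$n)) +
    ggplot2::geom_tile(colour = "grey70") +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(.data$n > 0, .data$n, "")),
                       size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2c7fb8") +
    ggplot2::labs(x = "predicted class", y = "true class",
                  title = paste0("Pooled confusion matrix: ", object$method),
                  fill = "count") +
    ggplot2::theme_minimal()
}

#' Method-comparison bar chart
#'
#' Compares evaluation reports (e.g. the naive baseline, the six base
#' classifiers and the three ensembles) on overall accuracy and macro-averaged
#' sensitivity/specificity/precision.
#'
#' @param reports A list of `rx_eval` objects.
#' @return A ggplot object.
#' @export
plot_method_comparison <- function(reports) {
  df <- dplyr::bind_rows(lapply(reports, glance))
  long <- tidyr::pivot_longer(
    df, c("accuracy", "macro_sensitivity", "macro_specificity",
          "macro_precision"),
    names_to = "metric", values_to = "percent"
  )
  long$method <- factor(long$method, levels = df$method)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$method, y = .data$percent,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::labs(x = NULL, y = "percent") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}
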