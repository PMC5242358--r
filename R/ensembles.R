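#' Learn multiplicative majority-vote weights
#'
#' The weighted-majority scheme behind weighted voting: every classifier
#' starts at weight 1 and, for each training sample it misclassifies, its
#' weight is multiplied by the update rate `beta`. The learned weight is
#' therefore exactly `beta ^ errors`. With `beta = 1` all weights stay 1 and
#' weighted voting reduces to plain majority voting. Weights are not
#' normalized — the vote argmax is scale-invariant.
#'
#' @param preds n-by-N matrix (or data frame) of hard class labels; column
#'   `j` holds classifier `j`'s predictions.
#' @param truth Length-n vector of true classes.
#' @param beta Update rate in `(0, 1]`.
#'
#' @return An `rx_weights` tibble with columns `classifier`, `errors`,
#'   `weight`, carrying `beta` as an attribute.
#' @export
#'
#' @examples
#' P <- cbind(a = c(1, 2, 2), b = c(1, 2, 1))
#' learn_weights(P, truth = c(1, 2, 2), beta = 0.5)
learn_weights <- function(preds, truth, beta) {
  P <- as.matrix(preds)
  if (!is.numeric(beta) || length(beta) != 1L || beta <= 0 || beta > 1) {
    abort("`beta` must lie in (0, 1].")
  }
  if (nrow(P) != length(truth)) {
    abort("`preds` rows must align with `truth`.")
  }
  errors <- colSums(P != as.integer(truth))
  nm <- colnames(P) %||% paste0("classifier_", seq_len(ncol(P)))
  out <- tibble::tibble(
    classifier = nm,
    errors = as.integer(errors),
    weight = beta ^ errors
  )
  structure(out, class = c("rx_weights", class(out)), beta = beta)
}

#' Combine hard class labels by (weighted) majority vote
#'
#' Each classifier casts its predicted class; the winning class maximizes the
#' sum of the voting classifiers' weights. Ties are broken in favour of the
#' class supported by the single heaviest classifier among the tied classes;
#' any remaining tie goes to the lowest class index. Tie events are reported
#' through a message so they stay auditable.
#'
#' @param preds n-by-N matrix of class labels, or a length-N vector for a
#'   single sample.
#' @param weights [learn_weights()] output, a numeric length-N vector, or
#'   `NULL` for equal weights (plain majority voting).
#' @param n_classes Number of classes `K`; defaults to the largest label seen.
#' @param quiet Suppress the tie message.
#'
#' @return Integer vector of combined labels with a logical `ties` attribute.
#' @export
#'
#' @examples
#' vote(rbind(c(1, 1, 2), c(2, 1, 1)))
#' vote(c(2, 1, 1), weights = c(3, 1, 1))
vote <- function(preds, weights = NULL, n_classes = NULL, quiet = FALSE) {
  P <- if (is.null(dim(preds))) matrix(as.integer(preds), nrow = 1L)
       else as.matrix(preds)
  if (ncol(P) == 0L) abort("cannot vote over an empty prediction row.")
  storage.mode(P) <- "integer"
  w <- if (is.null(weights)) rep(1, ncol(P))
       else if (inherits(weights, "rx_weights")) weights$weight
       else as.numeric(weights)
  if (length(w) != ncol(P)) {
    abort("`weights` must supply one weight per classifier column.")
  }
  if (any(w < 0)) abort("weights must be non-negative.")
  if (is.null(n_classes)) n_classes <- max(P)
  K <- as.integer(n_classes)
  if (min(P) < 1L || max(P) > K) abort("labels must lie in 1..n_classes.")

  n <- nrow(P)
  tally <- matrix(0, n, K)
  for (j in seq_len(ncol(P))) {
    idx <- cbind(seq_len(n), P[, j])
    tally[idx] <- tally[idx] + w[j]
  }

  win <- max.col(tally, ties.method = "first")
  top <- tally[cbind(seq_len(n), win)]
  tie <- rowSums(abs(tally - top) < 1e-9) > 1L

  if (any(tie)) {
    for (i in which(tie)) {
      tied <- which(abs(tally[i, ] - top[i]) < 1e-9)
      # heaviest single supporter among the tied classes wins
      best_w <- vapply(tied, function(cl) {
        sup <- w[P[i, ] == cl]
        if (length(sup)) max(sup) else 0
      }, 1)
      win[i] <- tied[which.max(best_w)]  # which.max -> lowest index on ties
    }
    if (!quiet) {
      inform(sprintf("%d vote(s) were tied; heaviest-supporter/lowest-index rule applied.",
                     sum(tie)))
    }
  }
  structure(as.integer(win), ties = tie)
}

# K-block one-hot encoding of an n x N hard-label matrix, so that a k-NN
# meta-learner sees Hamming geometry instead of a spurious ordinal scale.
onehot_predictions <- function(P, n_classes) {
  P <- as.matrix(P)
  n <- nrow(P)
  out <- matrix(0L, n, ncol(P) * n_classes)
  for (j in seq_len(ncol(P))) {
    out[cbind(seq_len(n), (j - 1L) * n_classes + P[, j])] <- 1L
  }
  out
}

#' Build a stacking meta-dataset from out-of-fold predictions
#'
#' Randomly divides the data into `J` equal-size parts (stratified by class so
#' every part retains all classes); for each part, every base learner is
#' trained on the other `J - 1` parts and predicts the held-out part. The
#' collected predictions plus the actual class form the next layer's data:
#' exactly `n` rows and `N + 1` columns, and no row is ever predicted by a
#' model whose training data contained it.
#'
#' @param data Feature tibble with `g1..gG` and `disease`.
#' @param specs Named list of [make_spec()] base-classifier specs.
#' @param J Number of parts (default 10).
#' @param seed Seed for the fold assignment.
#'
#' @return Tibble with columns `fold`, one prediction column per base
#'   classifier, and `disease`.
#' @export
build_meta_dataset <- function(data, specs, J = 10, seed = 1L) {
  y <- as.integer(data$disease)
  if (J < 2L) abort("`J` must be at least 2.")
  if (J > length(y)) abort("`J` cannot exceed the number of samples.")
  fold_id <- make_folds(y, J, seed)
  N <- length(specs)
  nm <- names(specs) %||% paste0("classifier_", seq_len(N))
  P <- matrix(NA_integer_, length(y), N, dimnames = list(NULL, nm))
  for (f in seq_len(J)) {
    test <- fold_id == f
    train <- data[!test, , drop = FALSE]
    for (j in seq_len(N)) {
      fitted <- fit(specs[[j]], train)
      P[test, j] <- predict(fitted, data[test, , drop = FALSE])
    }
  }
  out <- dplyr::bind_cols(
    tibble::tibble(fold = fold_id),
    tibble::as_tibble(P),
    tibble::tibble(disease = y)
  )
  out
}

#' Fit the stacking meta-learner and predict from base predictions
#'
#' Trains the second-layer learner — by default a 3-nearest-neighbour
#' classifier — on the meta-dataset's prediction columns versus the actual
#' class, and applies it to new rows of base predictions. Predicted labels
#' are one-hot encoded before the distance computation, since raw label
#' integers would impose a spurious ordinal metric on categorical votes.
#'
#' @param meta A [build_meta_dataset()] tibble (columns `fold`, predictions,
#'   `disease`).
#' @param new_preds n-by-N matrix/tibble of base predictions for new samples,
#'   with the meta-dataset's classifier columns.
#' @param meta_k Neighbour count of the k-NN meta-learner (default 3).
#' @param n_classes Number of classes; defaults to the largest label seen.
#' @param seed Seed pinning the meta-learner's neighbour tie-breaks.
#'
#' @return Integer vector of stacked class labels.
#' @export
stack_fit_predict <- function(meta, new_preds, meta_k = 3, n_classes = NULL,
                              seed = 1L) {
  pred_cols <- setdiff(names(meta), c("fold", "disease"))
  if (length(pred_cols) == 0L) abort("`meta` has no prediction columns.")
  newP <- as.matrix(as.data.frame(new_preds)[, pred_cols, drop = FALSE])
  trainP <- as.matrix(meta[pred_cols])
  if (ncol(newP) != ncol(trainP)) {
    abort("`new_preds` columns do not match the meta-dataset.")
  }
  y <- as.integer(meta$disease)
  if (is.null(n_classes)) n_classes <- max(trainP, newP, y)

  with_rng_seed(seed, {
    model <- e1071::gknn(onehot_predictions(trainP, n_classes),
                         factor(y, levels = sort(unique(y))),
                         k = meta_k, method = "manhattan", scale = FALSE)
    p <- predict(model, onehot_predictions(newP, n_classes), type = "class")
    as.integer(as.character(p))
  })
}

#' Ensemble specification for the cross-validation harness
#'
#' @param specs Named list of base [make_spec()] specifications.
#' @param method `"voting"` (equal weights), `"weighted_voting"`
#'   (multiplicative `beta` weights), or `"stacking"` (k-NN second layer).
#' @param beta Update rate for weighted voting. `NULL` (default) tunes it
#'   over `beta_grid`.
#' @param beta_grid Candidate update rates, default the grid from 0.1 to 1 in
#'   steps of 0.01.
#' @param inner_folds Inner fold count `J` used to learn weights /
#'   meta-datasets on the training folds only.
#' @param meta_k Meta-learner neighbour count for stacking.
#' @param resubstitution Learn voting weights from resubstitution errors
#'   (models predicting their own training data) instead of out-of-fold
#'   errors. Off by default: resubstitution rewards overfit learners.
#'
#' @return An `rx_ensemble_spec`.
#' @export
ensemble_spec <- function(specs,
                          method = c("voting", "weighted_voting", "stacking"),
                          beta = NULL,
                          beta_grid = seq(0.1, 1, by = 0.01),
                          inner_folds = 5,
                          meta_k = 3,
                          resubstitution = FALSE) {
  method <- match.arg(method)
  if (!is.null(beta) && (beta <= 0 || beta > 1)) {
    abort("`beta` must lie in (0, 1].")
  }
  if (length(beta_grid) == 0L || any(beta_grid <= 0) || any(beta_grid > 1)) {
    abort("`beta_grid` must be non-empty with values in (0, 1].")
  }
  structure(
    list(specs = specs, method = method, beta = beta,
         beta_grid = as.numeric(beta_grid),
         inner_folds = as.integer(inner_folds),
         meta_k = as.integer(meta_k),
         resubstitution = isTRUE(resubstitution),
         name = method),
    class = "rx_ensemble_spec"
  )
}

#' @export
print.rx_ensemble_spec <- function(x, ...) {
  cat(sprintf("<rx_ensemble_spec: %s> %d base classifiers\n",
              x$method, length(x$specs)))
  invisible(x)
}

#' Cross-validate the base-classifier bank and its ensembles in one pass
#'
#' The workhorse behind [cross_validate()] for ensembles and behind
#' [run_experiment()]. For each outer fold it (i) trains every base
#' classifier on the training folds and predicts the test fold — pooling
#' these gives each base classifier's own CV report for free; (ii) builds an
#' inner `J`-fold out-of-fold prediction matrix on the training folds, from
#' which voting weights are learned (weights = `beta ^ errors`) and on which
#' the stacking meta-learner is trained. Weighted-voting `beta` is tuned, if
#' requested, by evaluating every grid value's pooled test accuracy and
#' keeping the argmax (ties resolved towards the largest `beta`).
#'
#' @inheritParams ensemble_spec
#' @param data Feature tibble with `g1..gG` and `disease`.
#' @param folds Outer fold count (default 10).
#' @param seed Seed for fold assignments.
#' @param methods Ensemble methods to compute.
#' @param include_base Also return one `rx_eval` per base classifier.
#'
#' @return List with `reports` (named list of `rx_eval`), `best_beta`,
#'   `beta_table` (tibble of candidate `beta` and pooled accuracy), and
#'   `weights` (per-fold `rx_weights` at the selected `beta`).
#' @export
evaluate_methods <- function(data, specs, folds = 10, seed = 1L,
                             methods = c("voting", "weighted_voting",
                                         "stacking"),
                             beta = NULL,
                             beta_grid = seq(0.1, 1, by = 0.01),
                             inner_folds = 5, meta_k = 3,
                             resubstitution = FALSE,
                             include_base = TRUE) {
  methods <- match.arg(methods, several.ok = TRUE)
  y <- as.integer(data$disease)
  K <- max(y)
  n <- length(y)
  N <- length(specs)
  nm <- names(specs) %||% paste0("classifier_", seq_len(N))
  fold_id <- make_folds(y, folds, seed)

  base_pred <- matrix(NA_integer_, n, N, dimnames = list(NULL, nm))
  vote_pred <- integer(n)
  stack_pred <- integer(n)
  # per-fold error counts of each base classifier on its training folds
  fold_errors <- matrix(NA_real_, folds, N, dimnames = list(NULL, nm))
  weights_by_fold <- vector("list", folds)

  need_inner <- any(c("weighted_voting", "stacking") %in% methods)

  for (f in seq_len(folds)) {
    test <- fold_id == f
    train <- data[!test, , drop = FALSE]
    test_data <- data[test, , drop = FALSE]
    y_train <- y[!test]

    fits <- lapply(specs, fit, data = train)
    P_test <- vapply(fits, predict, integer(sum(test)),
                     new_data = test_data)
    P_test <- matrix(P_test, ncol = N, dimnames = list(NULL, nm))
    base_pred[test, ] <- P_test

    if ("voting" %in% methods) {
      vote_pred[test] <- vote(P_test, n_classes = K, quiet = TRUE)
    }

    if (need_inner) {
      if (resubstitution) {
        P_train <- vapply(fits, predict, integer(nrow(train)),
                          new_data = train)
        P_train <- matrix(P_train, ncol = N, dimnames = list(NULL, nm))
        meta <- dplyr::bind_cols(
          tibble::tibble(fold = rep(1L, nrow(train))),
          tibble::as_tibble(P_train),
          tibble::tibble(disease = y_train)
        )
      } else {
        meta <- build_meta_dataset(train, specs, J = inner_folds,
                                   seed = seed + f)
        P_train <- as.matrix(meta[nm])
      }
      fold_errors[f, ] <- colSums(P_train != y_train)
      if ("stacking" %in% methods) {
        stack_pred[test] <- stack_fit_predict(meta, P_test,
                                              meta_k = meta_k,
                                              n_classes = K,
                                              seed = seed + f)
      }
    }
  }

  reports <- list()
  if (include_base) {
    for (j in seq_len(N)) {
      reports[[nm[j]]] <- new_rx_eval(y, base_pred[, j], K, nm[j],
                                      folds, seed, fold_id)
    }
  }
  if ("voting" %in% methods) {
    reports$voting <- new_rx_eval(y, vote_pred, K, "voting", folds, seed,
                                  fold_id)
  }

  best_beta <- beta
  beta_table <- NULL
  if ("weighted_voting" %in% methods) {
    wv_for_beta <- function(b) {
      pred <- integer(n)
      for (f in seq_len(folds)) {
        test <- fold_id == f
        pred[test] <- vote(base_pred[test, , drop = FALSE],
                           weights = b ^ fold_errors[f, ],
                           n_classes = K, quiet = TRUE)
      }
      pred
    }
    if (is.null(best_beta)) {
      accs <- vapply(beta_grid, function(b) {
        mean(wv_for_beta(b) == y) * 100
      }, 1)
      beta_table <- tibble::tibble(beta = beta_grid, accuracy = accs)
      # argmax; ties resolved towards the largest beta
      best_beta <- max(beta_grid[accs >= max(accs) - 1e-12])
    }
    wv_pred <- wv_for_beta(best_beta)
    for (f in seq_len(folds)) {
      weights_by_fold[[f]] <- tibble::tibble(
        fold = f, classifier = nm,
        errors = as.integer(fold_errors[f, ]),
        weight = best_beta ^ fold_errors[f, ]
      )
    }
    reports$weighted_voting <- new_rx_eval(
      y, wv_pred, K, "weighted_voting", folds, seed, fold_id,
      extras = list(beta = best_beta)
    )
  }
  if ("stacking" %in% methods) {
    reports$stacking <- new_rx_eval(y, stack_pred, K, "stacking", folds,
                                    seed, fold_id,
                                    extras = list(meta_k = meta_k))
  }

  list(
    reports = reports,
    best_beta = best_beta,
    beta_table = beta_table,
    weights = if ("weighted_voting" %in% methods) {
      dplyr::bind_rows(weights_by_fold)
    }
  )
}

#' @export
cross_validate.rx_ensemble_spec <- function(data, model, folds = 10,
                                            seed = 1L, ...) {
  res <- evaluate_methods(
    data, model$specs, folds = folds, seed = seed,
    methods = model$method, beta = model$beta,
    beta_grid = model$beta_grid, inner_folds = model$inner_folds,
    meta_k = model$meta_k, resubstitution = model$resubstitution,
    include_base = FALSE
  )
  res$reports[[model$method]]
}

#' Tune the weighted-voting update rate
#'
#' Sweeps candidate update rates (default: 0.1 to 1 in steps of 0.01). For
#' each `beta`, weights are learned on the training folds only (from inner
#' out-of-fold error counts) and the cross-validated weighted-vote accuracy
#' is pooled over the outer test folds; the `beta` maximizing accuracy is
#' returned, ties resolved towards the largest value.
#'
#' @inheritParams evaluate_methods
#' @param grid Candidate `beta` values in `(0, 1]`.
#'
#' @return List with `best_beta` and `table` (tibble of `beta`, `accuracy`).
#' @export
tune_beta <- function(data, specs, grid = seq(0.1, 1, by = 0.01),
                      folds = 10, seed = 1L, inner_folds = 5,
                      resubstitution = FALSE) {
  if (length(grid) == 0L) abort("`grid` must be non-empty.")
  if (any(grid <= 0) || any(grid > 1)) abort("`grid` values must lie in (0, 1].")
  if (folds < 2L) abort("`folds` must be at least 2.")
  res <- evaluate_methods(
    data, specs, folds = folds, seed = seed, methods = "weighted_voting",
    beta = NULL, beta_grid = sort(unique(grid)), inner_folds = inner_folds,
    resubstitution = resubstitution, include_base = FALSE
  )
  list(best_beta = res$best_beta, table = res$beta_table)
}
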