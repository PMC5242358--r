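#' Configured base-classifier specifications
#'
#' Creates a classifier specification carrying the study's configured
#' hyperparameters for one of the six base learners, which downstream code
#' fits with [fit()] and applies with [predict()]. Defaults:
#'
#' * `decision_tree` — pruned classification tree, minimum leaf size 1,
#'   confidence factor 0.55. Backed by [rpart::rpart()]; a confidence factor
#'   above 0.5 effectively disables error-based pruning, mapped to
#'   `cp = 0` with `minsplit = 2`.
#' * `svm` — polynomial-kernel support vector machine, `C = 1.6`, degree 3;
#'   multiclass via one-vs-one with pairwise coupling of probability
#'   estimates. Backed by [e1071::svm()].
#' * `neural_net` — single hidden layer of 63 units over 60 inputs and K
#'   outputs, at most 500 optimization steps. Backed by [nnet::nnet()]
#'   (quasi-Newton optimizer; the classical learning-rate 0.3 / momentum 0.2
#'   settings are recorded in the spec but have no BFGS counterpart).
#' * `naive_bayes` — naive Bayes on factor-coded counts with Laplace
#'   smoothing 1. Backed by [e1071::naiveBayes()].
#' * `logistic_ridge` — multinomial logistic regression with ridge penalty
#'   (weight decay) 10. Backed by [nnet::multinom()].
#' * `knn` — nearest neighbour with `k = 1` and Manhattan distance. Backed by
#'   [e1071::gknn()].
#'
#' @param name One of `"decision_tree"`, `"svm"`, `"neural_net"`,
#'   `"naive_bayes"`, `"logistic_ridge"`, `"knn"`.
#' @param ... Named hyperparameter overrides; keys are validated against the
#'   learner's known hyperparameters.
#' @param seed Integer seed applied when fitting (stochastic learners).
#'
#' @return An object of class `rx_spec`.
#' @export
#'
#' @examples
#' make_spec("knn")
#' make_spec("svm", cost = 2.0)
make_spec <- function(name, ..., seed = 1L) {
  defaults <- list(
    decision_tree = list(min_leaf = 1L, confidence_factor = 0.55, cp = 0),
    svm = list(kernel = "polynomial", cost = 1.6, degree = 3L, coef0 = 1),
    neural_net = list(hidden = 63L, max_steps = 500L, learning_rate = 0.3,
                      momentum = 0.2, decay = 0),
    naive_bayes = list(laplace = 1),
    logistic_ridge = list(ridge = 10),
    knn = list(k = 1L, metric = "manhattan")
  )
  if (!name %in% names(defaults)) {
    abort(paste0("unknown classifier name: ", name, ". Known: ",
                 paste(names(defaults), collapse = ", "), "."))
  }
  hp <- defaults[[name]]
  overrides <- list(...)
  bad <- setdiff(names(overrides), names(hp))
  if (length(bad) > 0L || (length(overrides) > 0L && is.null(names(overrides)))) {
    abort(paste0("invalid hyperparameter(s) for ", name, ": ",
                 paste(bad, collapse = ", "), "."))
  }
  hp[names(overrides)] <- overrides

  structure(list(name = name, hyperparameters = hp, seed = as.integer(seed)),
            class = "rx_spec")
}

#' All six configured base-learner specifications
#'
#' @param seed Seed shared by all specs.
#' @return Named list of [make_spec()] objects in the canonical order.
#' @export
base_specs <- function(seed = 1L) {
  nm <- c("decision_tree", "svm", "neural_net", "naive_bayes",
          "logistic_ridge", "knn")
  setNames(lapply(nm, make_spec, seed = seed), nm)
}

#' @export
print.rx_spec <- function(x, ...) {
  hp <- paste(names(x$hyperparameters),
              vapply(x$hyperparameters, format, ""), sep = " = ",
              collapse = ", ")
  cat(sprintf("<rx_spec: %s> %s\n", x$name, hp))
  invisible(x)
}

#' Fit a configured classifier
#'
#' @param object An [make_spec()] specification.
#' @param data Feature tibble with drug-group columns `g1..gG` and a
#'   `disease` label column.
#' @param ... Unused.
#'
#' @return An `rx_fit` object with a [predict()] method returning integer
#'   class labels.
#' @method fit rx_spec
#' @export
fit.rx_spec <- function(object, data, ...) {
  X <- feature_matrix(data)
  if (nrow(X) == 0L) abort("cannot fit on an empty dataset.")
  if (!"disease" %in% names(data)) abort("`data` must have a `disease` column.")
  y <- as.integer(data$disease)
  classes <- sort(unique(y))
  if (length(classes) < 2L) {
    abort("at least two classes must be present in the training labels.")
  }
  yf <- factor(y, levels = classes)

  model <- with_rng_seed(object$seed, fit_engine(object, X, yf))

  structure(
    list(model = model, spec = object, classes = classes,
         n_features = ncol(X),
         fingerprint = c(n = nrow(X), checksum = sum(X) + sum(y))),
    class = "rx_fit"
  )
}

fit_engine <- function(spec, X, yf) {
  hp <- spec$hyperparameters
  df <- data.frame(X)
  df$.disease <- yf
  switch(
    spec$name,
    decision_tree = rpart::rpart(
      .disease ~ ., data = df, method = "class",
      control = rpart::rpart.control(
        minsplit = 2L * hp$min_leaf, minbucket = hp$min_leaf,
        cp = hp$cp, xval = 0L
      )
    ),
    svm = e1071::svm(
      X, yf, kernel = hp$kernel, cost = hp$cost, degree = hp$degree,
      coef0 = hp$coef0, probability = TRUE, scale = FALSE
    ),
    neural_net = nnet::nnet(
      X, nnet::class.ind(yf), size = hp$hidden, softmax = TRUE,
      maxit = hp$max_steps, decay = hp$decay, trace = FALSE,
      MaxNWts = 100000L
    ),
    naive_bayes = {
      lev <- lapply(seq_len(ncol(X)), function(j) sort(unique(X[, j])))
      fd <- as.data.frame(lapply(seq_len(ncol(X)), function(j) {
        factor(X[, j], levels = lev[[j]])
      }))
      names(fd) <- colnames(X)
      m <- e1071::naiveBayes(fd, yf, laplace = hp$laplace)
      list(model = m, levels = lev)
    },
    logistic_ridge = nnet::multinom(
      .disease ~ ., data = df, decay = hp$ridge, maxit = 500L,
      MaxNWts = 100000L, trace = FALSE
    ),
    knn = e1071::gknn(X, yf, k = hp$k, method = hp$metric, scale = FALSE),
    abort(paste0("no fitting engine for ", spec$name))
  )
}

#' @export
print.rx_fit <- function(x, ...) {
  cat(sprintf("<rx_fit: %s> trained on %d samples, %d features, %d classes\n",
              x$spec$name, x$fingerprint[["n"]], x$n_features,
              length(x$classes)))
  invisible(x)
}

#' Predict disease classes for new prescriptions
#'
#' @param object An `rx_fit` from [fit()].
#' @param new_data Feature tibble with the training drug-group columns.
#' @param ... Unused.
#'
#' @return Integer vector of class labels drawn from the training label set.
#' @export
predict.rx_fit <- function(object, new_data, ...) {
  X <- feature_matrix(new_data)
  if (ncol(X) != object$n_features) {
    abort(sprintf("new data has %d drug-group columns; the model was trained on %d.",
                  ncol(X), object$n_features))
  }
  if (nrow(X) == 0L) return(integer(0))
  classes <- object$classes
  hp <- object$spec$hyperparameters

  # some engines (e.g. the nearest-neighbour vote) break ties at random;
  # pin the stream so predictions are reproducible under the spec seed
  lab <- with_rng_seed(object$spec$seed, switch(
    object$spec$name,
    decision_tree = {
      p <- predict(object$model, data.frame(X), type = "class")
      as.integer(as.character(p))
    },
    svm = {
      # pairwise-coupled class probabilities from the one-vs-one machines
      pr <- attr(predict(object$model, X, probability = TRUE),
                 "probabilities")
      cls <- as.integer(colnames(pr))
      cls[max.col(pr, ties.method = "first")]
    },
    neural_net = {
      pr <- predict(object$model, X)
      as.integer(colnames(pr)[max.col(pr, ties.method = "first")])
    },
    naive_bayes = {
      lev <- object$model$levels
      fd <- as.data.frame(lapply(seq_len(ncol(X)), function(j) {
        factor(X[, j], levels = lev[[j]])  # unseen counts -> NA, ignored
      }))
      names(fd) <- colnames(X)
      p <- predict(object$model$model, fd)
      as.integer(as.character(p))
    },
    logistic_ridge = {
      p <- predict(object$model, data.frame(X))
      as.integer(as.character(p))
    },
    knn = {
      p <- predict(object$model, X, type = "class")
      as.integer(as.character(p))
    },
    abort("unknown fitted model type.")
  ))
  lab
}
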