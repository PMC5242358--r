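#' Configure an end-to-end prescription-classification experiment
#'
#' Bundles the simulation settings, the classifier bank, the ensemble
#' settings and the evaluation settings of one experiment.
#'
#' @param simulation An [sim_config()]; ignored when `data` is supplied to
#'   [run_experiment()].
#' @param methods Which methods to evaluate: any of `"naive"`, the six base
#'   classifier names, `"voting"`, `"weighted_voting"`, `"stacking"`.
#' @param folds Outer cross-validation folds (default 10).
#' @param seed Seed for fold assignment and classifier fitting.
#' @param beta Fixed weighted-voting update rate, or `NULL` to tune over
#'   `beta_grid`.
#' @param beta_grid Candidate update rates (default 0.1 to 1 by 0.01).
#' @param inner_folds Inner fold count for weight learning / stacking.
#' @param meta_k Stacking meta-learner neighbour count.
#' @param resubstitution Learn voting weights on resubstitution errors.
#' @param classifier_overrides Named list of named lists of hyperparameter
#'   overrides, e.g. `list(svm = list(cost = 2))`.
#'
#' @return An `rx_run_config`.
#' @export
run_config <- function(simulation = sim_config(),
                       methods = c("naive", "decision_tree", "svm",
                                   "neural_net", "naive_bayes",
                                   "logistic_ridge", "knn", "voting",
                                   "weighted_voting", "stacking"),
                       folds = 10,
                       seed = 1L,
                       beta = NULL,
                       beta_grid = seq(0.1, 1, by = 0.01),
                       inner_folds = 5,
                       meta_k = 3,
                       resubstitution = FALSE,
                       classifier_overrides = list()) {
  known <- c("naive", "decision_tree", "svm", "neural_net", "naive_bayes",
             "logistic_ridge", "knn", "voting", "weighted_voting", "stacking")
  bad <- setdiff(methods, known)
  if (length(bad) > 0L) {
    abort(paste0("unknown method(s): ", paste(bad, collapse = ", "), "."))
  }
  if (folds < 2L) abort("`folds` must be at least 2.")
  if (!is.null(beta) && (beta <= 0 || beta > 1)) {
    abort("`beta` must lie in (0, 1].")
  }
  if (length(beta_grid) == 0L || any(beta_grid <= 0) || any(beta_grid > 1)) {
    abort("`beta_grid` must be non-empty with values in (0, 1].")
  }
  structure(
    list(simulation = simulation, methods = methods,
         folds = as.integer(folds), seed = as.integer(seed),
         beta = beta, beta_grid = as.numeric(beta_grid),
         inner_folds = as.integer(inner_folds), meta_k = as.integer(meta_k),
         resubstitution = isTRUE(resubstitution),
         classifier_overrides = classifier_overrides),
    class = "rx_run_config"
  )
}

#' Run the full experiment: baseline, classifier bank, ensembles
#'
#' Reproduces the study workflow on synthetic (or supplied) data: generates
#' the dataset, evaluates the naive shared-drug-group baseline, each of the
#' six configured base classifiers, and the three combining techniques, all
#' under stratified 10-fold cross-validation with pooled confusion matrices,
#' and collects a method-comparison table. The base-classifier fits are
#' shared between the base reports and the ensembles, so the whole bundle
#' costs one pass of outer-fold fits plus the inner-fold fits used to learn
#' voting weights and stacking meta-data.
#'
#' @param config An [run_config()].
#' @param data Optional feature tibble (`g1..gG` + `disease`) to use instead
#'   of simulating; the naive baseline then needs `signatures`.
#' @param signatures Optional signature table (required for the naive
#'   baseline when `data` is supplied).
#' @param out_dir Optional directory; when given, the comparison table,
#'   per-method confusion matrices and metrics, learned weights, the beta
#'   tuning table, the dataset and the resolved configuration are written
#'   there as delimited text / YAML.
#' @param quiet Suppress per-stage progress messages.
#'
#' @return An `rx_experiment`: list with `reports` (named `rx_eval` list),
#'   `comparison` (tibble of [glance()] rows), `best_beta`, `beta_table`,
#'   `weights`, `dataset`, `config`.
#' @export
#'
#' @examples
#' \donttest{
#' cfg <- run_config(simulation = sim_config(n_prescriptions = 150,
#'                                           n_classes = 4, n_groups = 20,
#'                                           seed = 3),
#'                   methods = c("naive", "knn", "voting"),
#'                   folds = 5)
#' ex <- run_experiment(cfg)
#' ex$comparison
#' }
run_experiment <- function(config = run_config(), data = NULL,
                           signatures = NULL, out_dir = NULL,
                           quiet = FALSE) {
  stopifnot(inherits(config, "rx_run_config"))
  say <- function(...) if (!quiet) inform(sprintf(...))
  t0 <- Sys.time()

  dataset <- NULL
  if (is.null(data)) {
    say("stage simulate: generating %d prescriptions (K = %d, G = %d)",
        config$simulation$n_prescriptions, config$simulation$n_classes,
        config$simulation$n_groups)
    dataset <- generate_dataset(config$simulation)
    data <- dataset$features
    signatures <- dataset$signatures
  }

  base_names <- c("decision_tree", "svm", "neural_net", "naive_bayes",
                  "logistic_ridge", "knn")
  wanted_base <- intersect(base_names, config$methods)
  wanted_ens <- intersect(c("voting", "weighted_voting", "stacking"),
                          config$methods)

  reports <- list()

  if ("naive" %in% config$methods) {
    if (is.null(signatures)) {
      abort("the naive baseline needs a `signatures` table.")
    }
    say("stage naive: scoring against the %d-disease signature table",
        nrow(signatures))
    reports$naive <- suppressWarnings(
      cross_validate(data, naive_spec(signatures),
                     folds = config$folds, seed = config$seed)
    )
  }

  best_beta <- NULL
  beta_table <- NULL
  weights <- NULL
  if (length(wanted_base) > 0L || length(wanted_ens) > 0L) {
    specs <- base_specs(seed = config$seed)
    for (nm in names(config$classifier_overrides)) {
      ov <- config$classifier_overrides[[nm]]
      specs[[nm]] <- do.call(make_spec,
                             c(list(nm), ov, list(seed = config$seed)))
    }
    # ensembles always combine the full six-classifier bank
    eval_specs <- if (length(wanted_ens) > 0L) specs else specs[wanted_base]
    say("stage train/ensemble: %d-fold CV of %d base classifier(s)%s",
        config$folds, length(eval_specs),
        if (length(wanted_ens)) paste0(" + ", paste(wanted_ens, collapse = ", "))
        else "")
    res <- evaluate_methods(
      data, eval_specs, folds = config$folds, seed = config$seed,
      methods = if (length(wanted_ens) > 0L) wanted_ens else "voting",
      beta = config$beta, beta_grid = config$beta_grid,
      inner_folds = config$inner_folds, meta_k = config$meta_k,
      resubstitution = config$resubstitution,
      include_base = TRUE
    )
    if (length(wanted_ens) == 0L) {
      res$reports <- res$reports[setdiff(names(res$reports), "voting")]
    }
    keep <- c(wanted_base, wanted_ens)
    reports <- c(reports, res$reports[intersect(names(res$reports), keep)])
    best_beta <- res$best_beta
    beta_table <- res$beta_table
    weights <- res$weights
  }

  comparison <- dplyr::bind_rows(lapply(reports, glance))
  say("done in %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))

  out <- structure(
    list(reports = reports, comparison = comparison,
         best_beta = best_beta, beta_table = beta_table, weights = weights,
         dataset = dataset, config = config),
    class = "rx_experiment"
  )
  if (!is.null(out_dir)) write_experiment(out, out_dir)
  out
}

#' @export
print.rx_experiment <- function(x, ...) {
  cat(sprintf("<rx_experiment> %d method(s) evaluated\n", nrow(x$comparison)))
  print(x$comparison)
  if (!is.null(x$best_beta)) {
    cat(sprintf("weighted-voting beta = %.2f\n", x$best_beta))
  }
  invisible(x)
}

#' @method autoplot rx_experiment
#' @export
autoplot.rx_experiment <- function(object, ...) {
  plot_method_comparison(object$reports)
}

#' Write an experiment bundle to disk
#'
#' Writes `comparison.tsv`, per-method `confusion_<method>.tsv` and
#' `metrics_<method>.tsv`, `weights.tsv`, `beta_table.tsv`, the generated
#' dataset, and the resolved run configuration (`run_config.yaml`) so a
#' bundle carries its full audit trail.
#'
#' @param experiment An `rx_experiment`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(experiment, dir) {
  stopifnot(inherits(experiment, "rx_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(experiment$comparison, file.path(dir, "comparison.tsv"))
  for (nm in names(experiment$reports)) {
    ev <- experiment$reports[[nm]]
    cm <- as.data.frame(unclass(ev$confusion))
    names(cm) <- paste0("pred_", seq_len(ncol(cm)))
    readr::write_tsv(tibble::as_tibble(cm),
                     file.path(dir, paste0("confusion_", nm, ".tsv")))
    readr::write_tsv(ev$metrics, file.path(dir, paste0("metrics_", nm, ".tsv")))
  }
  if (!is.null(experiment$weights)) {
    readr::write_tsv(experiment$weights, file.path(dir, "weights.tsv"))
  }
  if (!is.null(experiment$beta_table)) {
    readr::write_tsv(experiment$beta_table, file.path(dir, "beta_table.tsv"))
  }
  if (!is.null(experiment$dataset)) {
    write_dataset(experiment$dataset, file.path(dir, "dataset"))
  }
  cfg <- experiment$config
  lst <- unclass(cfg)
  lst$simulation <- unclass(lst$simulation)
  lst$simulation$overlap_pairs <- lapply(lst$simulation$overlap_pairs,
                                         as.integer)
  if (!is.null(experiment$best_beta)) lst$selected_beta <- experiment$best_beta
  yaml::write_yaml(lst, file.path(dir, "run_config.yaml"))
  invisible(dir)
}
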