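#' Train the mitochondrial-morphology classifier
#'
#' Fits a random forest separating morphology classes (fragmented versus
#' tubular/hyperfused by default) from per-cell shape features, using
#' labelled training populations — the in-silico analogue of training on
#' DRP1- and OPA1-depleted cells. A stratified holdout is carved out before
#' fitting and the per-class holdout accuracy (the diagonal of the
#' confusion matrix) is recorded on the model.
#'
#' @param features per-cell feature table with a `class` column (e.g. from
#'   [featurize_morphology_set()]).
#' @param holdout_fraction stratified fraction reserved for evaluation
#'   (default 0.25).
#' @param seed integer seed (split and forest).
#' @param n_trees trees in the ensemble.
#' @return object of class `trained_classifier`: `model` (`rf_model`),
#'   `feature_names`, `class_labels`, `per_class_holdout_accuracy`,
#'   `confusion` (holdout confusion matrix), `importance`, `training_seed`.
#' @export
train_classifier <- function(features, holdout_fraction = 0.25, seed = 1L,
                             n_trees = 200L) {
  stopifnot("class" %in% names(features))
  y <- factor(features$class)
  if (nlevels(y) < 2) stop("need at least two classes to train")
  if (any(table(y) < 8))
    warning("fewer than 8 cells in some class; accuracy estimates unstable")
  fn <- intersect(feature_names(), names(features))
  x <- as.matrix(features[, fn, drop = FALSE])
  const <- apply(x, 2, function(v) length(unique(v)) == 1)
  if (any(const))
    warning("degenerate constant features: ",
            paste(fn[const], collapse = ", "))
  hold <- with_seed(seed, {
    unlist(lapply(levels(y), function(cl) {
      pool <- which(y == cl)
      sample(pool, max(1L, round(holdout_fraction * length(pool))))
    }))
  })
  model <- rf_fit(x[-hold, , drop = FALSE], y[-hold], n_trees = n_trees,
                  seed = seed)
  pred <- predict(model, x[hold, , drop = FALSE])
  truth <- y[hold]
  conf <- table(truth = truth, predicted = pred)
  acc <- diag(prop.table(conf, 1))
  structure(list(model = model, feature_names = fn,
                 class_labels = levels(y),
                 per_class_holdout_accuracy = acc,
                 confusion = conf, importance = model$importance,
                 training_seed = seed),
            class = "trained_classifier")
}

#' Score a cell population with a trained classifier
#'
#' Predicts the morphology class of every cell and reports the population
#' composition as percentages, the population-phenotype readout.
#'
#' @param model a [train_classifier()] result.
#' @param features per-cell feature table containing the training features.
#' @param sample_id identifier attached to the summary.
#' @return list of class `population_phenotype`: `sample_id`, `n_cells`,
#'   `percentages` (named, summing to 100), `calls` (per-cell factor).
#' @export
classify_population <- function(model, features, sample_id = "sample") {
  stopifnot(inherits(model, "trained_classifier"))
  if (nrow(features) == 0)
    stop("empty cell set: nothing to classify")
  missing <- setdiff(model$feature_names, names(features))
  if (length(missing) > 0)
    stop("missing features: ", paste(missing, collapse = ", "))
  calls <- predict(model$model,
                   features[, model$feature_names, drop = FALSE])
  pct <- 100 * prop.table(table(factor(calls,
                                       levels = model$class_labels)))
  structure(list(sample_id = sample_id, n_cells = nrow(features),
                 percentages = c(pct), calls = calls),
            class = "population_phenotype")
}

#' @export
print.trained_classifier <- function(x, ...) {
  cat("Morphology classifier (", x$model$n_trees, " trees)\n", sep = "")
  cat("Classes:", paste(x$class_labels, collapse = ", "), "\n")
  cat("Per-class holdout accuracy:\n")
  print(round(x$per_class_holdout_accuracy, 3))
  invisible(x)
}

#' @export
print.population_phenotype <- function(x, ...) {
  cat("Population phenotype for", x$sample_id, "(", x$n_cells, "cells )\n")
  print(round(x$percentages, 1))
  invisible(x)
}
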