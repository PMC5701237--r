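#' Stratified fold assignment
#'
#' Shuffles under `seed` and deals instances to folds class by class. With
#' `k` equal to the number of instances the partition is exactly
#' leave-one-out (singleton folds, stratification vacuous); otherwise every
#' class needs at least `k` members.
#'
#' @param label Factor of class labels.
#' @param k Number of folds.
#' @param seed Partition seed.
#' @return Integer fold id per instance.
#' @keywords internal
make_cv_folds <- function(label, k, seed) {
  n <- length(label)
  if (k < 2L) stop("k must be at least 2")
  if (k > n) stop("k exceeds the number of instances")
  if (k == n) return(seq_len(n))
  counts <- table(label)
  if (any(counts < k))
    stop("class '", names(counts)[which.min(counts)], "' has fewer than k = ",
         k, " instances; stratification impossible - consider jackknife()")
  fold <- integer(n)
  set.seed(seed)
  for (lv in levels(factor(label))) {
    idx <- which(label == lv)
    idx <- sample(idx)
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Stratified k-fold cross-validation with pooled confusion counts
#'
#' Instances are shuffled under `seed` and dealt to `k` folds class by
#' class (stratified). Each fold is held out once while a model is trained
#' on the remainder with `model_seed`; held-out confusion counts are pooled
#' over folds and the metrics computed once from the pooled table.
#' Per-fold (macro-averaged) metrics are reported separately and never
#' substituted for the pooled contract.
#'
#' With `k` equal to the instance count the partition is exactly
#' leave-one-out (singleton folds, no stratification needed); for
#' `k < n`, every class must have at least `k` members to stratify,
#' otherwise an error suggests the jackknife.
#'
#' @param dataset A [labeled_dataset()].
#' @param algorithm One of [rama_algorithms()].
#' @param hyperparameters As in [train_model()].
#' @param k Number of folds (default 10).
#' @param seed Seed for the fold partition.
#' @param model_seed Seed passed to every per-fold [train_model()] call
#'   (defaults to `seed`).
#' @param threshold Positive-call threshold (default 0.5).
#' @return List of class `rama_evaluation`: `metrics` (pooled), `counts`,
#'   `macro` (mean of per-fold metrics), `per_fold`, `scheme`.
#' @export
kfold_cv <- function(dataset, algorithm, hyperparameters = NULL, k = 10L,
                     seed = 1L, model_seed = seed, threshold = 0.5) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  n <- n_instances(dataset)
  fold <- make_cv_folds(dataset$label, k, seed)
  per_fold_counts <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- which(fold == f)
    train <- dataset_slice(dataset, -test_idx)
    model <- train_model(train, algorithm, hyperparameters, seed = model_seed)
    pred <- predict_class(model, dataset$features[test_idx, , drop = FALSE],
                          threshold)
    per_fold_counts[[f]] <- confusion_counts(dataset$label[test_idx], pred)
  }
  pooled <- pool_counts(per_fold_counts)
  per_fold <- lapply(per_fold_counts, function(cc)
    tryCatch(compute_metrics(cc), error = function(e) NULL))
  per_fold_mat <- do.call(rbind, per_fold)
  structure(list(metrics = compute_metrics(pooled), counts = pooled,
                 macro = if (!is.null(per_fold_mat))
                   colMeans(per_fold_mat, na.rm = TRUE) else NULL,
                 per_fold = per_fold_mat,
                 scheme = sprintf("%d-fold CV (seed %d)", k, seed)),
            class = "rama_evaluation")
}

#' Jackknife (leave-one-out) evaluation
#'
#' Each instance is held out in turn, a model is trained on the remaining
#' `n - 1` instances with the same `model_seed` every round, and the `n`
#' held-out predictions are pooled into one confusion table.
#'
#' @inheritParams kfold_cv
#' @return A `rama_evaluation` (no macro component: folds are singletons).
#' @export
jackknife <- function(dataset, algorithm, hyperparameters = NULL,
                      model_seed = 1L, threshold = 0.5) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  n <- n_instances(dataset)
  if (n < 2L) stop("jackknife needs at least 2 instances")
  pred <- character(n)
  for (i in seq_len(n)) {
    train <- dataset_slice(dataset, -i)
    model <- train_model(train, algorithm, hyperparameters, seed = model_seed)
    pred[i] <- as.character(
      predict_class(model, dataset$features[i, , drop = FALSE], threshold))
  }
  pooled <- confusion_counts(dataset$label, pred)
  structure(list(metrics = compute_metrics(pooled), counts = pooled,
                 macro = NULL, per_fold = NULL, scheme = "jackknife"),
            class = "rama_evaluation")
}

#' Evaluate a model trained on one species against another species
#'
#' The generality probe: a model trained on species A is assessed, in a
#' single pass, on the labeled dataset of species B. Same-species
#' evaluation is refused unless explicitly allowed.
#'
#' @param model A `rama_model` trained on species A.
#' @param dataset A [labeled_dataset()] of species B, same task.
#' @param threshold Positive-call threshold.
#' @param allow_same_species Permit A == B (default FALSE).
#' @return A `rama_evaluation` with `train_species` / `test_species`
#'   provenance fields.
#' @export
interspecies_test <- function(model, dataset, threshold = 0.5,
                              allow_same_species = FALSE) {
  stopifnot(inherits(model, "rama_model"), inherits(dataset, "labeled_dataset"))
  if (model$task != dataset$task)
    stop("task mismatch: model is ", model$task, ", dataset is ", dataset$task)
  if (!allow_same_species && identical(model$species, dataset$species))
    stop("train and test species are both '", model$species,
         "'; set allow_same_species = TRUE to override")
  pred <- predict_class(model, dataset$features, threshold)
  pooled <- confusion_counts(dataset$label, pred)
  structure(list(metrics = compute_metrics(pooled), counts = pooled,
                 macro = NULL, per_fold = NULL,
                 scheme = "inter-species",
                 train_species = model$species,
                 test_species = dataset$species),
            class = "rama_evaluation")
}

#' @export
print.rama_evaluation <- function(x, ...) {
  cat("<rama_evaluation>", x$scheme, "\n")
  print(round(x$metrics, 4))
  invisible(x)
}

#' Inter-species evaluation sweep over a set of datasets
#'
#' Trains one model per species and evaluates every ordered train/test
#' species pair (A != B), yielding the full s x (s - 1) report.
#'
#' @param datasets Named list of same-task [labeled_dataset()]s, one per
#'   species.
#' @param algorithm,hyperparameters,seed,threshold As in [kfold_cv()].
#' @return Data frame: `train_species`, `test_species`, six metric columns.
#' @export
interspecies_sweep <- function(datasets, algorithm, hyperparameters = NULL,
                               seed = 1L, threshold = 0.5) {
  species <- vapply(datasets, `[[`, character(1), "species")
  models <- lapply(datasets, train_model, algorithm = algorithm,
                   hyperparameters = hyperparameters, seed = seed)
  rows <- list()
  for (a in seq_along(datasets)) for (b in seq_along(datasets)) {
    if (a == b) next
    ev <- interspecies_test(models[[a]], datasets[[b]], threshold)
    rows[[length(rows) + 1L]] <-
      cbind(data.frame(train_species = species[a], test_species = species[b],
                       stringsAsFactors = FALSE),
            as.data.frame(as.list(ev$metrics)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
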