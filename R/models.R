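#' Supported learning algorithm identifiers
#' @return Character vector of the seven algorithm ids.
#' @export
rama_algorithms <- function() {
  c("multilayer-perceptron", "random-forest", "naive-bayes",
    "logitboost", "c45-tree", "svm-linear", "svm-rbf")
}

#' Frozen default hyperparameters per algorithm
#'
#' Defaults are frozen here (rather than inherited from the backing
#' libraries at run time) so trained models are stable across library
#' versions.
#'
#' @param algorithm One of [rama_algorithms()].
#' @return Named list of hyperparameters.
#' @export
default_hyperparameters <- function(algorithm) {
  switch(match.arg(algorithm, rama_algorithms()),
    "multilayer-perceptron" = list(size = 5L, decay = 0.1, maxit = 300L),
    "random-forest"         = list(ntree = 200L, mtry = 3L),
    "naive-bayes"           = list(laplace = 0),
    "logitboost"            = list(nIter = 50L),
    "c45-tree"              = list(minsplit = 10L, cp = 0.01),
    "svm-linear"            = list(cost = 1),
    "svm-rbf"               = list(cost = 1, gamma = 1 / 9))
}

#' Train a binary probabilistic classifier
#'
#' Fits one of the seven supported algorithm families on a labeled dataset.
#' Training is fully seeded: the same `(dataset, algorithm, hyperparameters,
#' seed)` yields identical probabilities. All models expose a calibrated (or
#' natively probabilistic) positive-class probability through
#' [predict_probability()]; the support-vector variants use the backing
#' library's built-in Platt-style probability calibration.
#'
#' @param dataset A [labeled_dataset()] containing both classes.
#' @param algorithm One of [rama_algorithms()].
#' @param hyperparameters Named list; `NULL` uses
#'   [default_hyperparameters()].
#' @param seed Integer seed for the stochastic parts of training.
#' @return Object of class `rama_model`: algorithm id, hyperparameters,
#'   dataset identity (species, task, instance count, feature hash), seed,
#'   and the fitted state.
#' @export
train_model <- function(dataset, algorithm, hyperparameters = NULL, seed = 1L) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  algorithm <- match.arg(algorithm, rama_algorithms())
  if (length(unique(dataset$label)) < 2L)
    stop("single-class dataset: cannot train a binary classifier")
  x <- dataset$features
  bad <- which(!is.finite(as.matrix(x)))
  if (length(bad)) {
    row <- (bad[1] - 1) %% nrow(x) + 1
    stop("non-finite feature value at instance '", dataset$ids[row], "'")
  }
  if (is.null(hyperparameters)) hyperparameters <- default_hyperparameters(algorithm)
  y <- dataset$label
  set.seed(seed)
  fit <- switch(algorithm,
    "random-forest" = randomForest::randomForest(
      x = x, y = y, ntree = hyperparameters$ntree, mtry = hyperparameters$mtry),
    "naive-bayes" = e1071::naiveBayes(
      x = x, y = y, laplace = hyperparameters$laplace),
    "multilayer-perceptron" = {
      ctr <- lapply(x, mean); scl <- lapply(x, stats::sd)
      scl <- lapply(scl, function(s) if (s == 0) 1 else s)
      xs <- as.data.frame(Map(function(v, m, s) (v - m) / s, x, ctr, scl))
      net <- nnet::nnet(xs, class_indicator(y), size = hyperparameters$size,
                        decay = hyperparameters$decay,
                        maxit = hyperparameters$maxit,
                        softmax = TRUE, trace = FALSE)
      list(net = net, center = ctr, scale = scl)
    },
    "logitboost" = caTools::LogitBoost(
      xlearn = as.matrix(x), ylearn = y, nIter = hyperparameters$nIter),
    "c45-tree" = rpart::rpart(
      label ~ ., data = cbind(x, label = y), method = "class",
      parms = list(split = "information"),
      control = rpart::rpart.control(minsplit = hyperparameters$minsplit,
                                     cp = hyperparameters$cp)),
    "svm-linear" = e1071::svm(
      x = x, y = y, kernel = "linear", cost = hyperparameters$cost,
      probability = TRUE, scale = TRUE),
    "svm-rbf" = e1071::svm(
      x = x, y = y, kernel = "radial", cost = hyperparameters$cost,
      gamma = hyperparameters$gamma, probability = TRUE, scale = TRUE))
  structure(list(algorithm = algorithm, hyperparameters = hyperparameters,
                 species = dataset$species, task = dataset$task,
                 n_train = n_instances(dataset),
                 dataset_hash = dataset_hash(dataset),
                 seed = as.integer(seed),
                 feature_names = attribute_names(),
                 levels = levels(dataset$label),
                 fit = fit,
                 created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
            class = "rama_model")
}

#' @keywords internal
class_indicator <- function(y) {
  m <- matrix(0, length(y), nlevels(y), dimnames = list(NULL, levels(y)))
  m[cbind(seq_along(y), as.integer(y))] <- 1
  m
}

#' @keywords internal
dataset_hash <- function(dataset) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(list(dataset$features, dataset$class_name), tmp)
  unname(tools::md5sum(tmp))
}

#' @export
print.rama_model <- function(x, ...) {
  cat("<rama_model>", x$algorithm, "| task:", x$task,
      "| species:", x$species, "| n:", x$n_train, "| seed:", x$seed, "\n")
  invisible(x)
}

#' Positive-class probability for new instances
#'
#' @param model A [train_model()] fit.
#' @param features A named numeric attribute vector, or a data frame with
#'   the nine attribute columns (one row per instance).
#' @return Numeric vector of probabilities in `[0, 1]`, one per instance.
#' @export
predict_probability <- function(model, features) {
  stopifnot(inherits(model, "rama_model"))
  if (is.numeric(features) && !is.null(names(features)))
    features <- as.data.frame(as.list(features))
  features <- as.data.frame(features)
  missing <- setdiff(model$feature_names, names(features))
  if (length(missing))
    stop("feature mismatch: missing attribute(s) ",
         paste(missing, collapse = ", "))
  x <- features[, model$feature_names, drop = FALSE]
  pos <- "positive"
  p <- switch(model$algorithm,
    "random-forest" = predict(model$fit, x, type = "prob")[, pos],
    "naive-bayes"   = predict(model$fit, x, type = "raw")[, pos],
    "multilayer-perceptron" = {
      xs <- as.data.frame(Map(function(v, m, s) (v - m) / s,
                              x, model$fit$center[names(x)],
                              model$fit$scale[names(x)]))
      predict(model$fit$net, xs, type = "raw")[, pos]
    },
    "logitboost" = {
      pr <- caTools::predict.LogitBoost(model$fit, as.matrix(x), type = "raw")
      pr <- pr / pmax(rowSums(pr), .Machine$double.eps)
      pr[, pos]
    },
    "c45-tree" = predict(model$fit, x, type = "prob")[, pos],
    "svm-linear" = ,
    "svm-rbf" = {
      pred <- predict(model$fit, x, probability = TRUE)
      attr(pred, "probabilities")[, pos]
    })
  unname(pmin(pmax(as.numeric(p), 0), 1))
}

#' Hard class prediction at a probability threshold
#' @param model A `rama_model`.
#' @param features As in [predict_probability()].
#' @param threshold Positive call iff probability >= threshold (default 0.5).
#' @return Factor with levels `negative`, `positive`.
#' @export
predict_class <- function(model, features, threshold = 0.5) {
  p <- predict_probability(model, features)
  factor(ifelse(p >= threshold, "positive", "negative"),
         levels = c("negative", "positive"))
}

#' Persist a trained model to a single file
#'
#' The archive carries the fitted state together with its metadata
#' (algorithm, hyperparameters, seed, training-set hash), so a loaded model
#' can be checked against the dataset it claims to come from.
#'
#' @param model A `rama_model`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "rama_model"))
  saveRDS(model, path)
  invisible(path)
}

#' Load a model saved by [save_model()]
#' @param path Model file.
#' @return A `rama_model`.
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "rama_model")) stop("'", path, "' is not a rama model")
  model
}

#' Select the best model by Matthews correlation coefficient
#'
#' Ties on MCC are broken by F-measure, residual ties by algorithm id
#' (lexicographic), so selection is deterministic.
#'
#' @param models List of `rama_model` objects.
#' @param metrics List of metric vectors from [compute_metrics()], parallel
#'   to `models`.
#' @return The winning model; its metrics are attached as attribute
#'   `"metrics"`.
#' @export
select_best <- function(models, metrics) {
  if (length(models) == 0L) stop("empty candidate collection")
  stopifnot(length(models) == length(metrics))
  mcc <- vapply(metrics, `[[`, numeric(1), "mcc")
  if (anyNA(mcc)) stop("candidate with undefined MCC")
  fm <- vapply(metrics, `[[`, numeric(1), "f_measure")
  algo <- vapply(models, `[[`, character(1), "algorithm")
  ord <- order(-mcc, -fm, algo)
  best <- models[[ord[1]]]
  attr(best, "metrics") <- metrics[[ord[1]]]
  best
}
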