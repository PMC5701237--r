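#' Two-stage ensemble configuration
#'
#' Bundles the stage-1 (RP vs NRP) and stage-2 (RP vs HP) model ensembles
#' with the discriminant probability threshold. Within a stage, per-model
#' positive-class probabilities are averaged; the mean is compared with the
#' threshold `T` (mean >= T is a positive stage call, including exact
#' equality).
#'
#' @param stage1 List of `rama_model`s with task `RP_vs_NRP`.
#' @param stage2 List of `rama_model`s with task `RP_vs_HP`.
#' @param threshold Discriminant probability T in (0, 1); default 0.5.
#'   A length-2 vector gives per-stage thresholds.
#' @return Object of class `ensemble_config`.
#' @export
ensemble_config <- function(stage1, stage2, threshold = 0.5) {
  if (inherits(stage1, "rama_model")) stage1 <- list(stage1)
  if (inherits(stage2, "rama_model")) stage2 <- list(stage2)
  if (length(stage1) == 0L || length(stage2) == 0L)
    stop("both stages need at least one model")
  if (!all(vapply(stage1, `[[`, character(1), "task") == "RP_vs_NRP"))
    stop("every stage-1 model must have task RP_vs_NRP")
  if (!all(vapply(stage2, `[[`, character(1), "task") == "RP_vs_HP"))
    stop("every stage-2 model must have task RP_vs_HP")
  threshold <- rep_len(as.numeric(threshold), 2L)
  if (any(threshold <= 0) || any(threshold >= 1))
    stop("threshold must lie strictly between 0 and 1")
  structure(list(stage1 = stage1, stage2 = stage2, threshold = threshold),
            class = "ensemble_config")
}

#' @export
print.ensemble_config <- function(x, ...) {
  cat("<ensemble_config> stage1:", length(x$stage1), "models | stage2:",
      length(x$stage2), "models | T:",
      paste(unique(x$threshold), collapse = "/"), "\n")
  invisible(x)
}

#' Ensemble probability: mean of per-model positive probabilities
#'
#' @param models List of task-compatible `rama_model`s.
#' @param features Attribute vector or data frame (see
#'   [predict_probability()]).
#' @return Mean probability per instance, in `[0, 1]`.
#' @export
ensemble_probability <- function(models, features) {
  if (inherits(models, "rama_model")) models <- list(models)
  if (length(models) == 0L) stop("empty model collection")
  tasks <- unique(vapply(models, `[[`, character(1), "task"))
  if (length(tasks) != 1L)
    stop("models mix tasks: ", paste(tasks, collapse = ", "))
  probs <- vapply(models, predict_probability, numeric(
    if (is.data.frame(features)) nrow(features) else 1L), features)
  if (is.null(dim(probs))) mean(probs) else rowMeans(probs)
}

#' Classify attribute vectors through the two-stage cascade
#'
#' Stage 1 averages the RP-vs-NRP ensemble probabilities; a mean below the
#' threshold stops the cascade with label `non-ribosomal` (stage 2 not
#' reached, its probability reported as `NA`). Otherwise the same instance
#' enters stage 2 (RP vs HP): a mean below the threshold yields
#' `histone-like`, and a mean at or above it in both stages yields
#' `ribosomal`.
#'
#' @param features One attribute vector or a data frame of instances.
#' @param config An [ensemble_config()].
#' @param ids Optional record identifiers.
#' @return Data frame of class `prediction_result`: `id`,
#'   `stage1_probability`, `stage2_probability`, `final_label` (factor:
#'   `non-ribosomal`, `histone-like`, `ribosomal`).
#' @export
classify <- function(features, config, ids = NULL) {
  stopifnot(inherits(config, "ensemble_config"))
  if (is.numeric(features) && !is.null(names(features)))
    features <- as.data.frame(as.list(features))
  features <- as.data.frame(features)
  n <- nrow(features)
  if (is.null(ids)) ids <- if (!is.null(features$id)) features$id
                           else sprintf("q%04d", seq_len(n))
  p1 <- ensemble_probability(config$stage1, features)
  p2 <- rep(NA_real_, n)
  pass1 <- p1 >= config$threshold[1]
  if (any(pass1))
    p2[pass1] <- ensemble_probability(config$stage2,
                                      features[pass1, , drop = FALSE])
  label <- rep("non-ribosomal", n)
  label[pass1] <- ifelse(p2[pass1] >= config$threshold[2],
                         "ribosomal", "histone-like")
  out <- data.frame(id = as.character(ids),
                    stage1_probability = p1,
                    stage2_probability = p2,
                    final_label = factor(label, levels = c(
                      "non-ribosomal", "histone-like", "ribosomal")),
                    stringsAsFactors = FALSE)
  class(out) <- c("prediction_result", "data.frame")
  out
}

#' Classify protein records end to end
#'
#' Convenience wrapper: extracts the nine attributes from the records and
#' runs [classify()].
#'
#' @param records Protein-record data frame ([parse_fasta()] output).
#' @param config An [ensemble_config()].
#' @param props A [residue_properties()] table.
#' @return A `prediction_result` data frame, one row per record.
#' @export
classify_records <- function(records, config, props = residue_properties()) {
  feats <- attributes_to_table(records, props)
  classify(feats[, attribute_names(), drop = FALSE], config,
           ids = feats$id)
}

#' Ranked report of predicted ribosomal proteins
#'
#' Classifies all records, keeps those called ribosomal, and orders them by
#' a combined score, descending. The default score is the minimum of the
#' two stage probabilities (a sequence is only as credible as its weaker
#' stage); the product is available as an alternative.
#'
#' @param records Protein-record data frame.
#' @param config An [ensemble_config()].
#' @param top_n Maximum rows returned (default 50).
#' @param score `"min"` (default) or `"product"`.
#' @param props A [residue_properties()] table.
#' @return The top `top_n` ribosomal calls with a `score` column, ordered
#'   by score descending (ties by id); the full three-way report is
#'   attached as attribute `"full_report"`.
#' @export
rank_candidates <- function(records, config, top_n = 50L,
                            score = c("min", "product"),
                            props = residue_properties()) {
  score <- match.arg(score)
  res <- classify_records(records, config, props)
  rib <- res[res$final_label == "ribosomal", , drop = FALSE]
  if (nrow(rib)) {
    rib$score <- switch(score,
      min     = pmin(rib$stage1_probability, rib$stage2_probability),
      product = rib$stage1_probability * rib$stage2_probability)
    rib <- rib[order(-rib$score, rib$id), , drop = FALSE]
    rib <- utils::head(rib, top_n)
  } else {
    rib$score <- numeric(0)
  }
  rownames(rib) <- NULL
  attr(rib, "full_report") <- res
  attr(rib, "score") <- score
  rib
}

#' Train the per-species model registry
#'
#' Fits one model per species and task over a benchmark's datasets: the
#' building blocks from which stage ensembles are drawn.
#'
#' @param benchmark Output of [default_benchmark()] (or the same shape).
#' @param algorithm One of [rama_algorithms()] (default random forest, the
#'   family that dominates the final pipeline).
#' @param hyperparameters As in [train_model()].
#' @param seed Training seed.
#' @return Object of class `model_registry`: nested list
#'   `registry[[species]][[task]]` of `rama_model`s.
#' @export
build_registry <- function(benchmark, algorithm = "random-forest",
                           hyperparameters = NULL, seed = 1L) {
  reg <- lapply(benchmark, function(sp) list(
    RP_vs_NRP = train_model(sp$datasets$RP_vs_NRP, algorithm,
                            hyperparameters, seed),
    RP_vs_HP  = train_model(sp$datasets$RP_vs_HP, algorithm,
                            hyperparameters, seed)))
  structure(reg, class = "model_registry")
}

#' Ensemble configuration for one test species from a registry
#'
#' @param registry A [build_registry()] result.
#' @param species The species to be classified.
#' @param include_self Include the model trained on `species` itself
#'   (default FALSE, the held-out protocol).
#' @param threshold Discriminant probability.
#' @return An [ensemble_config()] over the selected species' models.
#' @export
config_for_species <- function(registry, species, include_self = FALSE,
                               threshold = 0.5) {
  use <- if (include_self) names(registry) else setdiff(names(registry), species)
  if (length(use) == 0L) stop("no models left for species '", species, "'")
  ensemble_config(lapply(registry[use], `[[`, "RP_vs_NRP"),
                  lapply(registry[use], `[[`, "RP_vs_HP"),
                  threshold)
}

#' Leave-one-species-out evaluation of the whole pipeline
#'
#' For each species in the benchmark, an ensemble is built from the models
#' of the other species only and applied to that species' three-class
#' instance pool (RP, NRP, HP). A prediction is positive when the final
#' label is `ribosomal`; the truth is positive for RP instances. Confusion
#' counts are pooled across species before the metrics are computed.
#'
#' @param benchmark Output of [default_benchmark()].
#' @param registry A [build_registry()] result over the same benchmark.
#' @param threshold Discriminant probability.
#' @return List: `metrics` (pooled), `counts`, `per_species` (data frame of
#'   per-species metrics).
#' @export
pipeline_loso_eval <- function(benchmark, registry, threshold = 0.5) {
  counts <- list(); rows <- list()
  for (sp in names(benchmark)) {
    config <- config_for_species(registry, sp, include_self = FALSE,
                                 threshold = threshold)
    pool <- benchmark[[sp]]$instances
    res <- classify(pool$features, config, ids = pool$ids)
    truth <- ifelse(pool$class_name == "RP", "positive", "negative")
    call <- ifelse(res$final_label == "ribosomal", "positive", "negative")
    cc <- confusion_counts(truth, call)
    counts[[sp]] <- cc
    rows[[sp]] <- cbind(data.frame(species = sp, stringsAsFactors = FALSE),
                        as.data.frame(as.list(compute_metrics(cc))))
  }
  pooled <- pool_counts(counts)
  per_species <- do.call(rbind, rows)
  rownames(per_species) <- NULL
  list(metrics = compute_metrics(pooled), counts = pooled,
       per_species = per_species)
}
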