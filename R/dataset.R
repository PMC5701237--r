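#' Default annotation blocklist for the uncharacterized-protein filter
#' @return Character vector of keywords matched case-insensitively.
#' @export
default_blocklist <- function() {
  c("unknown", "uncharacterized", "hypothetical", "unnamed")
}

#' Remove unannotated and uncharacterized proteins
#'
#' A record is removed when its annotation is empty or matches any blocklist
#' keyword case-insensitively. This mirrors the training-set hygiene step of
#' dropping proteins with no functional annotation before class labels are
#' assigned.
#'
#' @param records Protein-record data frame.
#' @param blocklist Keywords; see [default_blocklist()].
#' @return The retained records; the number removed is reported with
#'   `message()`, and an empty result triggers a warning.
#' @export
filter_uncharacterized <- function(records, blocklist = default_blocklist()) {
  ann <- trimws(records$annotation)
  drop <- !nzchar(ann)
  for (kw in blocklist)
    drop <- drop | grepl(kw, ann, ignore.case = TRUE, fixed = FALSE)
  message(sum(drop), " of ", nrow(records),
          " records removed by annotation filter")
  kept <- records[!drop, , drop = FALSE]
  if (nrow(kept) == 0L) warning("annotation filter removed every record")
  rownames(kept) <- NULL
  kept
}

#' Labeled dataset constructor
#'
#' @param species Species tag.
#' @param task `"RP_vs_NRP"` or `"RP_vs_HP"`.
#' @param features Data frame of the nine attributes (rows = instances).
#' @param class_name Character vector in `{RP, NRP, HP}`, one per row.
#' @param ids Optional instance identifiers.
#' @param seed Seed used for any sampling during construction.
#' @return Object of class `labeled_dataset`: a list with the fields above
#'   plus `label`, a factor with levels `negative`/`positive` (positive iff
#'   `class_name == "RP"`).
#' @export
labeled_dataset <- function(species, task = c("RP_vs_NRP", "RP_vs_HP"),
                            features, class_name, ids = NULL, seed = NA_integer_) {
  task <- match.arg(task)
  features <- as.data.frame(features)[, attribute_names(), drop = FALSE]
  class_name <- as.character(class_name)
  stopifnot(nrow(features) == length(class_name))
  allowed <- if (task == "RP_vs_NRP") c("RP", "NRP") else c("RP", "HP")
  if (!all(class_name %in% allowed))
    stop("task ", task, " admits classes {", paste(allowed, collapse = ", "),
         "} only")
  if (length(unique(class_name)) < 2L)
    stop("dataset must contain at least one instance of each class")
  if (!all(vapply(features, is.numeric, logical(1))) ||
      !all(complete.cases(features)) || !all(is.finite(as.matrix(features))))
    stop("features must be finite numeric values")
  label <- factor(ifelse(class_name == "RP", "positive", "negative"),
                  levels = c("negative", "positive"))
  if (is.null(ids)) ids <- sprintf("i%04d", seq_len(nrow(features)))
  structure(list(species = species, task = task, features = features,
                 class_name = class_name, label = label,
                 ids = as.character(ids), seed = seed),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("<labeled_dataset> species:", x$species, " task:", x$task, "\n")
  print(table(x$class_name))
  invisible(x)
}

#' Number of instances in a labeled dataset
#' @param dataset A `labeled_dataset`.
#' @return Integer count.
#' @export
n_instances <- function(dataset) nrow(dataset$features)

#' Subset a labeled dataset by row indices
#' @keywords internal
dataset_slice <- function(dataset, idx) {
  labeled_dataset(dataset$species, dataset$task,
                  dataset$features[idx, , drop = FALSE],
                  dataset$class_name[idx], ids = dataset$ids[idx],
                  seed = dataset$seed)
}

#' Assemble a training dataset with negative subsampling
#'
#' For the ribosomal vs non-ribosomal task, the negative pool is reduced by
#' seeded sampling (with replacement by default) to `ceiling(ratio x
#' n_positives)` instances, the enforced 3:1 class ratio that avoids
#' majority-class bias without discarding positive diversity. For the
#' ribosomal vs histone task no subsampling is applied: all negatives are
#' kept, as histone sets are small and balanced enough already.
#'
#' @param positives Feature data frame of the positive (RP) instances.
#' @param negatives Feature data frame of the negative pool (NRP or HP).
#' @param task `"RP_vs_NRP"` (subsampled) or `"RP_vs_HP"` (kept whole).
#' @param species Species tag recorded in the dataset.
#' @param ratio Negative:positive ratio for `RP_vs_NRP`; default 3.
#' @param seed Integer seed for the subsampling draw (required for
#'   `RP_vs_NRP`).
#' @param replace Sample negatives with replacement (default TRUE).
#' @param positive_ids,negative_ids Optional instance identifiers.
#' @return A [labeled_dataset()].
#' @export
assemble_dataset <- function(positives, negatives,
                             task = c("RP_vs_NRP", "RP_vs_HP"),
                             species = "unknown", ratio = 3, seed = 1L,
                             replace = TRUE,
                             positive_ids = NULL, negative_ids = NULL) {
  task <- match.arg(task)
  positives <- as.data.frame(positives)
  negatives <- as.data.frame(negatives)
  if (nrow(positives) == 0L) stop("empty positive pool")
  if (nrow(negatives) == 0L) stop("empty negative pool")
  if (ratio <= 0) stop("ratio must be positive")
  if (is.null(positive_ids)) positive_ids <- sprintf("pos%04d", seq_len(nrow(positives)))
  if (is.null(negative_ids)) negative_ids <- sprintf("neg%04d", seq_len(nrow(negatives)))
  if (task == "RP_vs_NRP") {
    n_neg <- as.integer(ceiling(ratio * nrow(positives)))
    set.seed(seed)
    pick <- sample.int(nrow(negatives), n_neg, replace = replace)
    negatives <- negatives[pick, , drop = FALSE]
    negative_ids <- negative_ids[pick]
    neg_class <- "NRP"
  } else {
    neg_class <- "HP"
  }
  labeled_dataset(
    species, task,
    features = rbind(positives[, attribute_names(), drop = FALSE],
                     negatives[, attribute_names(), drop = FALSE]),
    class_name = c(rep("RP", nrow(positives)),
                   rep(neg_class, nrow(negatives))),
    ids = c(positive_ids, negative_ids),
    seed = as.integer(seed))
}
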