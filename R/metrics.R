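#' Confusion counts from truth and prediction vectors
#'
#' @param truth Factor/character of true labels.
#' @param predicted Factor/character of predicted labels.
#' @param positive The label treated as positive (default `"positive"`).
#' @return Object of class `confusion_counts`: list with integer `TP`,
#'   `TN`, `FP`, `FN`.
#' @export
confusion_counts <- function(truth, predicted, positive = "positive") {
  stopifnot(length(truth) == length(predicted))
  t_pos <- truth == positive
  p_pos <- predicted == positive
  structure(list(TP = sum(t_pos & p_pos), TN = sum(!t_pos & !p_pos),
                 FP = sum(!t_pos & p_pos), FN = sum(t_pos & !p_pos)),
            class = "confusion_counts")
}

#' Pool several confusion-count objects by summing
#' @param ... `confusion_counts` objects (or a single list of them).
#' @return A pooled `confusion_counts`.
#' @export
pool_counts <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && !inherits(xs[[1]], "confusion_counts")) xs <- xs[[1]]
  structure(list(TP = as.integer(sum(vapply(xs, `[[`, numeric(1), "TP"))),
                 TN = as.integer(sum(vapply(xs, `[[`, numeric(1), "TN"))),
                 FP = as.integer(sum(vapply(xs, `[[`, numeric(1), "FP"))),
                 FN = as.integer(sum(vapply(xs, `[[`, numeric(1), "FN")))),
            class = "confusion_counts")
}

#' Binary classification metrics from confusion counts
#'
#' Applies the six standard formulas literally:
#' precision = TP/(TP+FP); accuracy = (TP+TN)/(TP+FN+FP+TN);
#' sensitivity = TP/(TP+FN); specificity = TN/(FP+TN);
#' F-measure = 2TP/(2TP+FP+FN);
#' MCC = (TP·TN − FP·FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
#' A metric whose denominator is zero is returned as `NA` (undefined), never
#' silently zeroed.
#'
#' @param counts A [confusion_counts()] object, or a list with fields
#'   `TP`, `TN`, `FP`, `FN`.
#' @return Named numeric vector: `precision`, `accuracy`, `sensitivity`,
#'   `specificity`, `f_measure`, `mcc`.
#' @examples
#' compute_metrics(list(TP = 90, FN = 10, TN = 70, FP = 30))
#' @export
compute_metrics <- function(counts) {
  TP <- as.numeric(counts$TP); TN <- as.numeric(counts$TN)
  FP <- as.numeric(counts$FP); FN <- as.numeric(counts$FN)
  if (anyNA(c(TP, TN, FP, FN)) || any(c(TP, TN, FP, FN) < 0))
    stop("confusion counts must be non-negative numbers")
  if (TP + TN + FP + FN == 0) stop("no evaluated instances")
  div <- function(num, den) if (den == 0) NA_real_ else num / den
  mcc_den <- sqrt((TP + FP) * (TP + FN) * (TN + FP) * (TN + FN))
  c(precision   = div(TP, TP + FP),
    accuracy    = div(TP + TN, TP + FN + FP + TN),
    sensitivity = div(TP, TP + FN),
    specificity = div(TN, FP + TN),
    f_measure   = div(2 * TP, 2 * TP + FP + FN),
    mcc         = div(TP * TN - FP * FN, mcc_den))
}
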