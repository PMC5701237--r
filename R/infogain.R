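#' Shannon entropy of a class label vector, in bits
#'
#' \eqn{H = -\sum_i p_i \log_2 p_i}, with \eqn{0 \log 0 := 0}.
#'
#' @param labels Vector (factor or character) of class labels.
#' @return Entropy in bits.
#' @examples
#' class_entropy(c("a", "a", "b", "b"))  # 1 bit
#' @export
class_entropy <- function(labels) {
  if (length(labels) == 0L) stop("empty label collection")
  p <- table(labels)
  p <- p[p > 0] / length(labels)
  -sum(p * log2(p))
}

#' Equal-frequency discretization
#'
#' @param values Numeric vector.
#' @param bins Target number of bins (default 10); duplicate quantiles
#'   collapse, so fewer bins may result.
#' @return Integer bin assignment, values in `1..n_bins`.
#' @export
discretize_efreq <- function(values, bins = 10L) {
  qs <- unique(stats::quantile(values, probs = seq(0, 1, length.out = bins + 1),
                               names = FALSE, type = 7))
  if (length(qs) <= 2L) return(rep(1L, length(values)))
  cuts <- qs[-c(1, length(qs))]
  findInterval(values, cuts, left.open = TRUE) + 1L
}

#' MDL-based supervised discretization (Fayyad-Irani)
#'
#' Recursively bisects the sorted attribute at the boundary minimizing the
#' class entropy of the partition, accepting a split only when the
#' information gain exceeds the minimum-description-length criterion
#' \deqn{gain > \frac{\log_2(N-1)}{N} + \frac{\log_2(3^k-2) - kH(S) +
#'   k_1 H(S_1) + k_2 H(S_2)}{N}}
#' where \eqn{k} counts classes present in each subset. An attribute on
#' which no split is accepted collapses to a single bin (and hence zero
#' information gain).
#'
#' @param values Numeric attribute column.
#' @param labels Class labels, same length.
#' @return Integer bin assignment.
#' @export
discretize_mdl <- function(values, labels) {
  stopifnot(length(values) == length(labels))
  cuts <- .mdl_cuts(values, as.character(labels))
  if (length(cuts) == 0L) return(rep(1L, length(values)))
  findInterval(values, sort(cuts), left.open = TRUE) + 1L
}

#' @keywords internal
.mdl_cuts <- function(values, labels) {
  ord <- order(values)
  v <- values[ord]; l <- labels[ord]
  recurse <- function(lo, hi) {
    n <- hi - lo + 1L
    if (n < 2L) return(numeric(0))
    vv <- v[lo:hi]; ll <- l[lo:hi]
    ent_all <- class_entropy(ll)
    if (ent_all == 0) return(numeric(0))
    # candidate cuts: midpoints between adjacent distinct values
    distinct <- which(diff(vv) > 0)
    if (length(distinct) == 0L) return(numeric(0))
    best_gain <- -Inf; best_i <- NA_integer_; best_e1 <- NA; best_e2 <- NA
    for (i in distinct) {
      e1 <- class_entropy(ll[1:i])
      e2 <- class_entropy(ll[(i + 1):n])
      w <- i / n
      gain <- ent_all - (w * e1 + (1 - w) * e2)
      if (gain > best_gain) {
        best_gain <- gain; best_i <- i; best_e1 <- e1; best_e2 <- e2
      }
    }
    k  <- length(unique(ll))
    k1 <- length(unique(ll[1:best_i]))
    k2 <- length(unique(ll[(best_i + 1):n]))
    delta <- log2(3^k - 2) - (k * ent_all - k1 * best_e1 - k2 * best_e2)
    threshold <- (log2(n - 1) + delta) / n
    if (best_gain <= threshold) return(numeric(0))
    cut <- (vv[best_i] + vv[best_i + 1]) / 2
    c(recurse(lo, lo + best_i - 1L), cut, recurse(lo + best_i, hi))
  }
  recurse(1L, length(v))
}

#' Information gain of an attribute about the class
#'
#' \eqn{IG = H(class) - H(class \mid attrib)}, where the conditional term is
#' the bin-size-weighted mean class entropy over the discretized attribute.
#'
#' @param values Numeric attribute column.
#' @param labels Class labels, same length (>= 2).
#' @param discretizer `"mdl"` (default), `"efreq"`, or a function
#'   `f(values, labels)` returning an integer bin assignment.
#' @param bins Bin count for `"efreq"`.
#' @return Information gain in bits (non-negative).
#' @export
information_gain <- function(values, labels, discretizer = "mdl", bins = 10L) {
  stopifnot(length(values) == length(labels), length(values) >= 2L)
  bin <- if (is.function(discretizer)) {
    discretizer(values, labels)
  } else {
    switch(match.arg(discretizer, c("mdl", "efreq")),
           mdl   = discretize_mdl(values, labels),
           efreq = discretize_efreq(values, bins))
  }
  h <- class_entropy(labels)
  n <- length(labels)
  cond <- 0
  for (b in unique(bin)) {
    in_bin <- bin == b
    cond <- cond + sum(in_bin) / n * class_entropy(labels[in_bin])
  }
  max(h - cond, 0)
}

#' Rank the nine attributes by information gain
#'
#' @param dataset A [labeled_dataset()].
#' @param discretizer As in [information_gain()].
#' @param bins Bin count for `"efreq"`.
#' @return Data frame of class `ig_report` with columns `attribute`, `ig`,
#'   `rank` (1 = most informative; ties broken by attribute name,
#'   ascending), ordered by rank, and attributes `species`, `task`,
#'   `class_entropy`.
#' @export
rank_attributes <- function(dataset, discretizer = "mdl", bins = 10L) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  ig <- vapply(attribute_names(), function(a)
    information_gain(dataset$features[[a]], dataset$class_name,
                     discretizer, bins), numeric(1))
  ord <- order(-ig, names(ig))
  rep_df <- data.frame(attribute = names(ig)[ord],
                       ig = unname(ig)[ord],
                       rank = seq_along(ig),
                       stringsAsFactors = FALSE)
  attr(rep_df, "species") <- dataset$species
  attr(rep_df, "task") <- dataset$task
  attr(rep_df, "class_entropy") <- class_entropy(dataset$class_name)
  class(rep_df) <- c("ig_report", "data.frame")
  rep_df
}

#' Class-conditional distribution summaries per attribute
#'
#' Produces the tabular data behind per-class density (or histogram)
#' visualizations of each attribute: for every attribute and every class
#' with at least two instances, a Gaussian kernel density evaluated on a
#' fixed grid shared across classes, or histogram counts on shared breaks.
#'
#' @param datasets A `labeled_dataset` or list of them (classes are pooled
#'   by `class_name` across datasets).
#' @param type `"density"` (default) or `"histogram"`.
#' @param grid_n Grid size for densities (default 512) or bin count for
#'   histograms (default 30 when `type = "histogram"`).
#' @return Long-format data frame: `attribute`, `class`, `x`, `y` (density)
#'   or `count`; the grid/breaks used are recorded as attributes. Classes
#'   with fewer than two instances are omitted with a warning.
#' @export
class_conditional_summaries <- function(datasets, type = c("density", "histogram"),
                                        grid_n = NULL) {
  type <- match.arg(type)
  if (inherits(datasets, "labeled_dataset")) datasets <- list(datasets)
  if (is.null(grid_n)) grid_n <- if (type == "density") 512L else 30L
  feats <- do.call(rbind, lapply(datasets, `[[`, "features"))
  cls <- unlist(lapply(datasets, `[[`, "class_name"))
  too_small <- names(which(table(cls) < 2L))
  for (cl in too_small)
    warning("class '", cl, "' has < 2 instances; its summaries are omitted")
  out <- list()
  for (a in attribute_names()) {
    v <- feats[[a]]
    rng <- range(v)
    if (type == "histogram")
      breaks <- seq(rng[1], rng[2], length.out = grid_n + 1L)
    for (cl in setdiff(unique(cls), too_small)) {
      vv <- v[cls == cl]
      if (type == "density") {
        d <- stats::density(vv, n = grid_n, from = rng[1], to = rng[2])
        out[[length(out) + 1L]] <-
          data.frame(attribute = a, class = cl, x = d$x, y = d$y,
                     bandwidth = d$bw, stringsAsFactors = FALSE)
      } else {
        h <- graphics::hist(vv, breaks = breaks, plot = FALSE)
        out[[length(out) + 1L]] <-
          data.frame(attribute = a, class = cl, x = h$mids, count = h$counts,
                     stringsAsFactors = FALSE)
      }
    }
  }
  res <- do.call(rbind, out)
  attr(res, "type") <- type
  attr(res, "grid_n") <- grid_n
  res
}
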