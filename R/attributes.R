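#' Compute the nine classification attributes of one sequence
#'
#' The five group attributes are proportions: the count of residues in the
#' group divided by the total sequence length. The three mean attributes
#' (hydrophobicity, molecular mass, volume) are arithmetic means of the
#' per-residue table values over the standard residues. Length is the total
#' residue count. Ambiguity codes count toward length, belong to no group,
#' and are excluded from the three means; a sequence with no standard
#' residue is an error.
#'
#' @param sequence One uppercase amino acid sequence, or a one-row
#'   protein-record data frame.
#' @param props A [residue_properties()] table.
#' @param ambiguity Accepted non-standard codes.
#' @return Named numeric vector of length 9 (see [attribute_names()]).
#' @examples
#' compute_attributes("KRH")[["positively_charged"]]  # 1
#' @export
compute_attributes <- function(sequence, props = residue_properties(),
                               ambiguity = default_ambiguity_codes()) {
  if (is.data.frame(sequence)) sequence <- sequence$sequence[1]
  stopifnot(is.character(sequence), length(sequence) == 1L)
  out <- sequence_attribute_matrix(sequence, props, ambiguity)
  stats::setNames(as.numeric(out[1, ]), colnames(out))
}

#' Attribute matrix for a vector of sequences
#'
#' Vectorized core of [compute_attributes()].
#'
#' @inheritParams compute_attributes
#' @param sequences Character vector of uppercase sequences.
#' @return Numeric matrix, one row per sequence, nine attribute columns.
#' @keywords internal
sequence_attribute_matrix <- function(sequences, props = residue_properties(),
                                      ambiguity = default_ambiguity_codes()) {
  groups <- residue_groups()
  std <- props$residue
  alphabet <- c(std, ambiguity)
  n <- length(sequences)
  out <- matrix(NA_real_, n, 9L, dimnames = list(NULL, attribute_names()))
  group_cols <- c("aromatic", "negatively_charged", "nonpolar_aliphatic",
                  "polar_uncharged", "positively_charged")
  for (i in seq_len(n)) {
    chars <- strsplit(sequences[i], "", fixed = TRUE)[[1]]
    len <- length(chars)
    if (len == 0L) stop("empty sequence at index ", i)
    idx <- match(chars, alphabet)
    if (anyNA(idx))
      stop("illegal character '", chars[which(is.na(idx))[1]],
           "' at position ", which(is.na(idx))[1], " (sequence ", i, ")")
    counts <- tabulate(idx, nbins = length(alphabet))
    std_counts <- counts[seq_along(std)]
    n_std <- sum(std_counts)
    if (n_std == 0L)
      stop("sequence ", i, " contains no standard residue; ",
           "mean attributes are undefined")
    for (k in seq_along(groups))
      out[i, group_cols[k]] <-
        sum(std_counts[std %in% groups[[k]]]) / len
    out[i, "hydrophobicity"] <- sum(std_counts * props$hydropathy) / n_std
    out[i, "molecular_mass"] <- sum(std_counts * props$mass) / n_std
    out[i, "volume"]         <- sum(std_counts * props$volume) / n_std
    out[i, "length"]         <- len
  }
  out
}

#' Feature table for a collection of protein records
#'
#' @param records Protein-record data frame ([parse_fasta()] output).
#' @param props A [residue_properties()] table.
#' @param ambiguity Accepted non-standard codes.
#' @return Data frame with columns `id`, `species` and the nine attributes,
#'   row order matching the input. An empty record collection yields an
#'   empty table with the full header.
#' @export
attributes_to_table <- function(records, props = residue_properties(),
                                ambiguity = default_ambiguity_codes()) {
  if (nrow(records) == 0L) {
    empty <- as.data.frame(matrix(numeric(0), 0, 9,
                                  dimnames = list(NULL, attribute_names())))
    return(cbind(data.frame(id = character(0), species = character(0),
                            stringsAsFactors = FALSE), empty))
  }
  mat <- tryCatch(
    sequence_attribute_matrix(records$sequence, props, ambiguity),
    error = function(e) stop("attribute extraction failed (record '",
                             records$id[1], "' collection): ",
                             conditionMessage(e), call. = FALSE))
  cbind(data.frame(id = records$id, species = records$species,
                   stringsAsFactors = FALSE),
        as.data.frame(mat))
}

#' Write a feature table as TSV
#'
#' Numeric attribute values are formatted to six decimal places (length as
#' an integer), matching the precision the attributes are reported at.
#'
#' @param table Feature table from [attributes_to_table()], optionally with
#'   a `class` column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_tsv <- function(table, path) {
  out <- table
  for (nm in setdiff(attribute_names(), "length"))
    if (nm %in% names(out)) out[[nm]] <- sprintf("%.6f", out[[nm]])
  if ("length" %in% names(out)) out$length <- as.integer(out$length)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_tsv()]
#' @param path TSV path.
#' @return Data frame.
#' @export
read_feature_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write a feature table as ARFF
#'
#' @param table Feature table; if `class` is present it is written as a
#'   nominal attribute.
#' @param path Output path.
#' @param relation ARFF relation name.
#' @return `path`, invisibly.
#' @export
write_feature_arff <- function(table, path, relation = "rama_features") {
  out <- table
  if ("class" %in% names(out)) out$class <- factor(out$class)
  foreign::write.arff(out, path, relation = relation)
  invisible(path)
}

#' Read an ARFF feature table
#' @param path ARFF path.
#' @return Data frame.
#' @export
read_feature_arff <- function(path) foreign::read.arff(path)
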