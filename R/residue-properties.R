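#' Residue chemistry table
#'
#' Per-residue physicochemical properties of the 20 standard amino acids:
#' Kyte-Doolittle hydropathy index, free-amino-acid molecular mass (integer
#' Mr convention, daltons), residue volume (cubic angstroms, Zamyatnin), and
#' membership in exactly one of five chemical groups. The five groups
#' partition the standard alphabet: aromatic (F, Y, W), negatively-charged
#' (D, E), nonpolar-aliphatic (G, A, P, V, L, I, M), polar-uncharged
#' (S, T, C, N, Q), and positively-charged (K, H, R).
#'
#' The shipped table is calibration-gated: the package test suite requires
#' it to reproduce, to six decimal places, all nine attribute values of a
#' reference 62-residue ribosomal protein whose expected values are frozen
#' in the tests.
#'
#' @param path Optional path to an alternative property table (TSV with
#'   columns `residue`, `hydropathy`, `mass`, `volume`, `group`; `#` lines
#'   are comments). Defaults to the table shipped with the package.
#' @return A data frame of class `residue_property_table` with one row per
#'   standard residue and row names the one-letter codes.
#' @examples
#' props <- residue_properties()
#' props["K", ]
#' @export
residue_properties <- function(path = NULL) {
  if (is.null(path)) {
    cached <- .rama_env$residue_properties
    if (!is.null(cached)) return(cached)
    path <- system.file("extdata", "residue_properties.tsv", package = "rama",
                        mustWork = TRUE)
    tab <- .read_property_table(path)
    .rama_env$residue_properties <- tab
    return(tab)
  }
  .read_property_table(path)
}

.rama_env <- new.env(parent = emptyenv())

#' @keywords internal
.read_property_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  validate_property_table(tab)
  rownames(tab) <- tab$residue
  class(tab) <- c("residue_property_table", "data.frame")
  tab
}

#' The five residue groups and their member residues
#' @return Named list mapping group name to one-letter residue codes.
#' @export
residue_groups <- function() {
  list(
    "aromatic"            = c("F", "Y", "W"),
    "negatively-charged"  = c("D", "E"),
    "nonpolar-aliphatic"  = c("G", "A", "P", "V", "L", "I", "M"),
    "polar-uncharged"     = c("S", "T", "C", "N", "Q"),
    "positively-charged"  = c("K", "H", "R")
  )
}

#' @keywords internal
validate_property_table <- function(tab) {
  need <- c("residue", "hydropathy", "mass", "volume", "group")
  if (!all(need %in% names(tab)))
    stop("property table must have columns: ", paste(need, collapse = ", "))
  if (nrow(tab) != 20L || anyDuplicated(tab$residue))
    stop("property table must have exactly 20 unique residues, got ",
         nrow(tab))
  groups <- residue_groups()
  if (!setequal(tab$residue, unlist(groups)))
    stop("property table residues are not the 20 standard one-letter codes")
  for (g in names(groups)) {
    got <- sort(tab$residue[tab$group == g])
    if (!identical(got, sort(groups[[g]])))
      stop("group '", g, "' does not match the standard partition")
  }
  for (col in c("hydropathy", "mass", "volume"))
    if (!is.numeric(tab[[col]]) || anyNA(tab[[col]]))
      stop("column '", col, "' must be numeric and complete")
  invisible(tab)
}

#' Names of the nine classification attributes
#' @return Character vector in canonical column order.
#' @export
attribute_names <- function() {
  c("aromatic", "negatively_charged", "nonpolar_aliphatic",
    "polar_uncharged", "positively_charged",
    "hydrophobicity", "molecular_mass", "volume", "length")
}

#' Default ambiguity codes accepted in sequences
#'
#' Ambiguous or nonstandard codes count toward sequence length but belong to
#' no chemical group and are excluded from the three mean attributes.
#' @return Character vector of single letters.
#' @export
default_ambiguity_codes <- function() c("X", "B", "Z", "U", "O")
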