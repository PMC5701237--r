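#' Read amino acid sequences from a FASTA file
#'
#' Parses a multi-record protein FASTA file into a protein-record data frame.
#' Sequences are uppercased and a single trailing `*` stop symbol is
#' stripped; the part of the header line after the first whitespace is kept
#' as free-text annotation. Any character outside the 20 standard residues
#' and the configured ambiguity codes is a parse error reported with the
#' offending record and position (an internal `*` is such an error).
#'
#' @param path Path to a FASTA file.
#' @param species Species tag attached to every record (free text).
#' @param ambiguity Accepted non-standard codes; see
#'   [default_ambiguity_codes()].
#' @return A data frame with columns `id`, `species`, `sequence`,
#'   `annotation`, one row per record, in file order.
#' @examples
#' fa <- system.file("extdata", "example.fasta", package = "rama")
#' parse_fasta(fa, species = "A. thaliana")
#' @export
parse_fasta <- function(path, species = "unknown",
                        ambiguity = default_ambiguity_codes()) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("cannot read FASTA '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (length(set) == 0L) stop("FASTA file '", path, "' contains no records")
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  annotation <- ifelse(grepl("\\s", headers),
                       sub("^\\S+\\s+", "", headers), "")
  if (any(!nzchar(ids)))
    stop("malformed FASTA header (empty identifier) at record ",
         which(!nzchar(ids))[1])
  seqs <- toupper(as.character(set))
  seqs <- sub("\\*$", "", seqs)
  protein_records(id = ids, species = species, sequence = seqs,
                  annotation = annotation, ambiguity = ambiguity)
}

#' Construct and validate a protein-record table
#'
#' @param id Character identifiers.
#' @param species Species tag(s), recycled.
#' @param sequence Uppercase amino acid sequences.
#' @param annotation Optional free-text annotations (recycled; default "").
#' @param ambiguity Accepted non-standard codes.
#' @return Data frame with columns `id`, `species`, `sequence`, `annotation`.
#' @export
protein_records <- function(id, species, sequence, annotation = "",
                            ambiguity = default_ambiguity_codes()) {
  sequence <- toupper(sequence)
  rec <- data.frame(id = as.character(id), species = as.character(species),
                    sequence = sequence,
                    annotation = as.character(annotation),
                    stringsAsFactors = FALSE)
  alphabet <- c(residue_groups() |> unlist() |> unname(), ambiguity)
  for (i in seq_len(nrow(rec))) {
    s <- rec$sequence[i]
    if (!nzchar(s))
      stop("record '", rec$id[i], "': empty sequence")
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    bad <- which(!(chars %in% alphabet))
    if (length(bad))
      stop("record '", rec$id[i], "': illegal character '", chars[bad[1]],
           "' at position ", bad[1])
  }
  rownames(rec) <- NULL
  rec
}

#' Write protein records as FASTA
#'
#' @param records Protein-record data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- ifelse(nzchar(records$annotation),
                       paste(records$id, records$annotation),
                       records$id)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
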