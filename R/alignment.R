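# Alignment container and FASTA I/O.  An alignment is a plain character
# matrix: taxa in rows (unique rownames), sites in columns, uppercase
# nucleotides with N (or -) as missing data.  Codon frame starts at column 1.

#' Validate and normalize an alignment matrix
#'
#' @param x a character matrix with unique rownames.
#' @return the normalized (uppercase) matrix.
#' @keywords internal
#' @export
validate_alignment <- function(x) {
  if (!is.matrix(x) || !is.character(x)) {
    stop("alignment must be a character matrix (taxa x sites)", call. = FALSE)
  }
  if (is.null(rownames(x)) || any(!nzchar(rownames(x)))) {
    stop("alignment rows must be named by taxon", call. = FALSE)
  }
  dup <- rownames(x)[duplicated(rownames(x))]
  if (length(dup)) {
    stop("duplicate taxon label(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  toupper(x)
}

#' Read a multi-FASTA alignment
#'
#' @param path path to a FASTA file of equal-length nucleotide sequences.
#' @return a character matrix (taxa x sites), uppercase.
#' @seealso [write_fasta()]
#' @export
read_fasta <- function(path) {
  recs <- ape::read.FASTA(path)
  if (length(recs) == 0) stop("no sequences in ", path, call. = FALSE)
  lens <- lengths(recs)
  if (any(lens != lens[1])) {
    bad <- which(lens != lens[1])[1]
    stop(sprintf(
      "ragged alignment: record '%s' has length %d, expected %d",
      names(recs)[bad], lens[bad], lens[1]), call. = FALSE)
  }
  chars <- as.character(recs)
  if (is.list(chars)) chars <- do.call(rbind, chars)
  m <- toupper(chars)
  rownames(m) <- names(recs)
  validate_alignment(m)
}

#' Write an alignment to FASTA
#'
#' @param alignment a character matrix (taxa x sites).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_fasta <- function(alignment, path) {
  alignment <- validate_alignment(alignment)
  ape::write.FASTA(ape::as.DNAbin(tolower(alignment)), file = path)
  invisible(path)
}
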