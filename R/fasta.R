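# FASTA input/output. Parsing is delegated to Biostrings; this layer adds
# the concatenation contract the compressor needs: uppercased record
# sequences joined in order, an optional single separator byte between
# records, and a record table mapping each record to its offset in the
# concatenation.

#' Read a FASTA file as one concatenated sequence
#'
#' Records are uppercased and concatenated in file order, optionally joined
#' by a single separator byte (which must not occur inside any sequence).
#' Non-ACGT characters (N, IUPAC codes, protein letters) pass through as
#' ordinary bytes.
#'
#' @param path path to a FASTA file (multi-record; wrapped or unwrapped
#'   lines).
#' @param separator optional single character or byte value inserted between
#'   records.
#' @return A list with `sequence` (character scalar) and `records` (a
#'   data.frame with `id`, `offset` (0-based position in the concatenation)
#'   and `length`).
#' @export
read_fasta_concat <- function(path, separator = NULL) {
  lines <- readLines(path, warn = FALSE)
  first <- which(nzchar(trimws(lines)))[1L]
  if (is.na(first)) stop(sprintf("%s: line 1: empty FASTA file", path))
  if (!startsWith(lines[first], ">")) {
    stop(sprintf("%s: line %d: expected a '>' FASTA header before sequence data",
                 path, first))
  }
  x <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(x))
  ids <- names(x)
  if (is.null(ids)) ids <- paste0("record", seq_along(seqs))
  sep <- ""
  if (!is.null(separator)) {
    sep <- if (is.character(separator)) separator else bytes_to_text(as.integer(separator))
    if (nchar(sep, type = "bytes") != 1L) {
      stop("separator must be a single byte")
    }
    hit <- which(vapply(seqs, function(s) grepl(sep, s, fixed = TRUE), logical(1)))
    if (length(hit)) {
      stop(sprintf("separator byte occurs inside sequence record %d ('%s')",
                   hit[1L], ids[hit[1L]]))
    }
  }
  lens <- nchar(seqs, type = "bytes")
  gaps <- if (nzchar(sep)) 1L else 0L
  offsets <- cumsum(c(0L, lens[-length(lens)] + gaps))
  list(sequence = paste(seqs, collapse = sep),
       records = data.frame(id = ids, offset = as.integer(offsets),
                            length = as.integer(lens)))
}

#' Write named sequences to a FASTA file
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line wrap width (default 60).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  x <- Biostrings::BStringSet(seqs)
  if (is.null(names(seqs))) names(x) <- paste0("record", seq_along(seqs))
  Biostrings::writeXStringSet(x, filepath = path, width = as.integer(width))
  invisible(path)
}
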