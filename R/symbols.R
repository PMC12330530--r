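# Byte-level helpers shared across the package.
#
# All public coordinates are 0-based (positions in texts, symbol ids);
# internal vectors use R's native 1-based indexing. Symbol ids 0..sigma-1
# denote terminals (the bytes present in the inputs, numbered in ascending
# byte order); ids >= sigma denote non-terminals in creation order.

text_to_bytes <- function(x) {
  if (is.raw(x)) return(as.integer(x))
  if (is.character(x) && length(x) == 1L) return(as.integer(charToRaw(x)))
  if (is.numeric(x)) return(as.integer(x))
  stop("expected a single character string, a raw vector, or an integer vector")
}

bytes_to_text <- function(b) rawToChar(as.raw(b))

#' Build a terminal alphabet over one or more texts
#'
#' Terminal ids are assigned by ascending byte value over the union of bytes
#' present in the supplied texts, so that the numbering is deterministic and
#' independent of which text a byte first appears in.
#'
#' @param ... texts (character scalars, raw vectors, or integer byte vectors).
#' @return A list with `sigma` (alphabet size), `byte_map` (integer vector of
#'   byte values for terminal ids `0..sigma-1`) and `byte2id` (a 256-slot
#'   lookup table, `NA` for absent bytes).
#' @export
alphabet_over <- function(...) {
  bs <- sort(unique(unlist(lapply(list(...), text_to_bytes))))
  byte2id <- rep(NA_integer_, 256L)
  byte2id[bs + 1L] <- seq_along(bs) - 1L
  list(sigma = length(bs), byte_map = as.integer(bs), byte2id = byte2id)
}

# text -> 0-based terminal ids under `alpha`
encode_ids <- function(text, alpha) {
  b <- text_to_bytes(text)
  ids <- alpha$byte2id[b + 1L]
  if (anyNA(ids)) stop("text contains bytes outside the alphabet")
  ids
}

# 0-based terminal ids -> text
decode_ids <- function(ids, alpha) bytes_to_text(alpha$byte_map[ids + 1L])
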