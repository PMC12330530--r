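# Synthetic repetitive collections: many near-identical copies of a base
# sequence, emulating the pangenome-style datasets reference-based
# compressors are built for. Fully deterministic under a seed.

mutate_copy <- function(base_chars, substitution_rate, indel_rate, alphabet) {
  v <- base_chars
  n <- length(v)
  if (substitution_rate > 0) {
    hit <- which(stats::runif(n) < substitution_rate)
    if (length(hit)) {
      # substitute with a different character than the current one
      cur <- match(v[hit], alphabet)
      shift <- sample.int(length(alphabet) - 1L, length(hit), replace = TRUE)
      v[hit] <- alphabet[((cur - 1L + shift) %% length(alphabet)) + 1L]
    }
  }
  if (indel_rate > 0) {
    ev <- which(stats::runif(length(v)) < indel_rate)
    # apply right to left so earlier positions stay valid
    for (pos in rev(ev)) {
      len <- stats::rgeom(1L, 0.5) + 1L
      if (stats::runif(1L) < 0.5) {
        ins <- sample(alphabet, len, replace = TRUE)
        v <- append(v, ins, after = pos)
      } else {
        drop <- pos:min(pos + len - 1L, length(v))
        v <- v[-drop]
        if (length(v) == 0L) v <- sample(alphabet, 1L)
      }
    }
  }
  v
}

#' Generate a synthetic repetitive collection
#'
#' Draws a random base sequence and derives `num_copies` mutated copies
#' (per-position substitutions at `substitution_rate`; geometric-length
#' insertions/deletions triggered at `indel_rate` per position). The target
#' collection is the set of copies; the reference is the base sequence,
#' optionally extended with the first `reference_copies` copies (emulating a
#' reference subsampled from the collection itself). Identical arguments,
#' including the seed, always produce identical output.
#'
#' @param base_length length of the base sequence (> 0).
#' @param num_copies number of mutated copies in the target collection.
#' @param substitution_rate per-position substitution probability in [0,1].
#' @param indel_rate per-position indel probability in [0,1].
#' @param alphabet character vector of single characters (default A,C,G,T).
#' @param seed integer seed; all randomness derives from it.
#' @param reference_copies how many target copies to append to the reference
#'   (default 0: the base sequence alone).
#' @return A list with `reference` and `target`: named character vectors of
#'   FASTA-ready records.
#' @export
generate_collection <- function(base_length, num_copies,
                                substitution_rate = 0.01,
                                indel_rate = 0.001,
                                alphabet = c("A", "C", "G", "T"),
                                seed = 1L,
                                reference_copies = 0L) {
  if (base_length < 1L) stop("base_length must be positive")
  if (num_copies < 1L) stop("num_copies must be positive")
  if (substitution_rate < 0 || substitution_rate > 1 ||
      indel_rate < 0 || indel_rate > 1) {
    stop("rates must lie in [0, 1]")
  }
  if (length(alphabet) < 2L) stop("alphabet needs at least two characters")
  withr::with_seed(as.integer(seed), {
    base_chars <- sample(alphabet, base_length, replace = TRUE)
    copies <- vapply(seq_len(num_copies), function(i) {
      paste(mutate_copy(base_chars, substitution_rate, indel_rate, alphabet),
            collapse = "")
    }, character(1))
    names(copies) <- sprintf("copy_%03d", seq_len(num_copies))
    ref <- c(base = paste(base_chars, collapse = ""))
    k <- min(reference_copies, num_copies)
    if (k > 0L) ref <- c(ref, copies[seq_len(k)])
    list(reference = ref, target = copies)
  })
}
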