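# Ground-truth oracles: a deliberately simple array-based RePair with a full
# recount every round, and a brute-force bigram counter. Both are used to
# validate the interval-based engine; neither shares code with it.

#' Naive RePair (reference implementation)
#'
#' Straightforward RePair over a plain symbol array: count all bigrams from
#' scratch each round, replace the most frequent one (same tie and run
#' policies as the engine) leftmost-first and non-overlapping, and repeat
#' until no bigram occurs more than once.
#'
#' @param text character scalar or raw vector, non-empty.
#' @param tie_policy `"lex"` (smallest (left,right) pair, default) or
#'   `"insertion"` (bigram first seen earliest, scanning left to right round
#'   by round).
#' @param run_policy `"first"` (default; replace the first occurrence in a
#'   run of identical symbols, as the engine does) or `"last"` (replace the
#'   last occurrence, emulating Navarro's RePair — same number of
#'   replacements, different grammar symbols).
#' @param alphabet optionally, an [alphabet_over()] alphabet to number
#'   terminals with; defaults to the bytes of `text`. Supplying the engine's
#'   target-plus-reference alphabet makes the two grammars comparable symbol
#'   for symbol.
#' @return A grammar object (see [new_grammar()]).
#' @export
naive_repair <- function(text, tie_policy = c("lex", "insertion"),
                         run_policy = c("first", "last"),
                         alphabet = NULL) {
  tie_policy <- match.arg(tie_policy)
  run_policy <- match.arg(run_policy)
  alpha <- if (is.null(alphabet)) alphabet_over(text) else alphabet
  v <- encode_ids(text, alpha)
  if (length(v) < 1L) stop("text must be non-empty")
  seen <- new.env(parent = emptyenv())
  clock <- 0L
  next_id <- alpha$sigma
  rules <- matrix(integer(0), ncol = 3L,
                  dimnames = list(NULL, c("lhs", "left", "right")))
  repeat {
    n <- length(v)
    if (n < 2L) break
    keys <- paste0(v[-n], "_", v[-1L])
    if (tie_policy == "insertion") {
      for (k in unique(keys)) {
        if (is.null(seen[[k]])) {
          clock <- clock + 1L
          seen[[k]] <- clock
        }
      }
    }
    ct <- table(keys)
    m <- max(ct)
    if (m < 2L) break
    cand <- names(ct)[ct == m]
    parts <- do.call(rbind, strsplit(cand, "_", fixed = TRUE))
    ca <- as.integer(parts[, 1L])
    cb <- as.integer(parts[, 2L])
    pick <- if (tie_policy == "lex") {
      order(ca, cb)[1L]
    } else {
      which.min(vapply(cand, function(k) seen[[k]], integer(1)))
    }
    a <- ca[pick]; b <- cb[pick]
    z <- next_id
    rules <- rbind(rules, c(z, a, b))
    next_id <- next_id + 1L
    out <- integer(n)
    oi <- 0L
    if (run_policy == "first") {
      i <- 1L
      while (i <= n) {
        if (i < n && v[i] == a && v[i + 1L] == b) {
          oi <- oi + 1L; out[oi] <- z; i <- i + 2L
        } else {
          oi <- oi + 1L; out[oi] <- v[i]; i <- i + 1L
        }
      }
      v <- out[seq_len(oi)]
    } else {
      # rightmost-first within runs: greedy right-to-left scan
      i <- n
      while (i >= 1L) {
        if (i > 1L && v[i - 1L] == a && v[i] == b) {
          oi <- oi + 1L; out[oi] <- z; i <- i - 2L
        } else {
          oi <- oi + 1L; out[oi] <- v[i]; i <- i - 1L
        }
      }
      v <- rev(out[seq_len(oi)])
    }
  }
  new_grammar(alpha$sigma, alpha$byte_map, rules, v)
}

#' Brute-force bigram counts
#'
#' Counts every adjacent symbol pair of a sequence. The total mass is
#' `length(seq) - 1` for non-empty sequences; overlapping pairs in runs are
#' all counted.
#'
#' @param ids integer vector of symbol ids (or a character scalar, counted
#'   over its bytes).
#' @return Named integer vector; names are `"a_b"` id pairs.
#' @export
bigram_counts <- function(ids) {
  if (is.character(ids)) ids <- text_to_bytes(ids)
  n <- length(ids)
  if (n < 2L) return(structure(integer(0), names = character(0)))
  keys <- paste0(ids[-n], "_", ids[-1L])
  tab <- table(keys)
  structure(as.integer(tab), names = names(tab))
}
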