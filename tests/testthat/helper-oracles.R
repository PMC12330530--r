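# Brute-force helpers independent of the package's matching machinery:
# longest matches via R's fixed-string search, and small random texts.

brute_longest_match <- function(ref, q) {
  maxl <- min(nchar(ref), nchar(q))
  for (l in rev(seq_len(maxl))) {
    p <- regexpr(substr(q, 1L, l), ref, fixed = TRUE, useBytes = TRUE)
    if (p > 0L) return(list(len = l, pos = as.integer(p) - 1L))
  }
  list(len = 0L, pos = NA_integer_)
}

# quadratic-time greedy factorizer (leftmost source position on ties)
brute_rlz <- function(target, ref) {
  n <- nchar(target)
  pos <- integer(0); len <- integer(0); lit <- logical(0); byte <- integer(0)
  t0 <- 1L
  while (t0 <= n) {
    m <- brute_longest_match(ref, substr(target, t0, n))
    if (m$len == 0L) {
      pos <- c(pos, NA_integer_); len <- c(len, 1L); lit <- c(lit, TRUE)
      byte <- c(byte, as.integer(charToRaw(substr(target, t0, t0))))
      t0 <- t0 + 1L
    } else {
      pos <- c(pos, m$pos); len <- c(len, m$len); lit <- c(lit, FALSE)
      byte <- c(byte, NA_integer_)
      t0 <- t0 + m$len
    }
  }
  data.frame(pos = pos, len = len, literal = lit, byte = byte)
}

rand_str <- function(n, alpha = c("A", "C", "G", "T")) {
  paste(sample(alpha, n, replace = TRUE), collapse = "")
}

# grammar equality at the structural level (rules + start sequence)
expect_same_grammar <- function(g1, g2) {
  expect_identical(unname(g1$rules), unname(g2$rules))
  expect_identical(g1$start_sequence, g2$start_sequence)
  expect_identical(g1$byte_map, g2$byte_map)
}
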