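# Relative Lempel-Ziv parsing: greedy factorization of a target text into
# maximal substrings of a reference, each encoded as a (position, length)
# pair. The matcher is a suffix array of the reference queried by binary
# search; comparisons run under C collation so ordering is plain byte order.

#' Build a longest-match index over a reference
#'
#' Constructs a suffix array of the reference. Queries report the longest
#' prefix of a pattern occurring in the reference together with the leftmost
#' occurrence position, equivalent in output to a brute-force scan over all
#' substrings.
#'
#' @param reference character scalar or raw vector; must be non-empty.
#' @return An object of class `rlz_index`.
#' @export
rlz_index <- function(reference) {
  ref <- if (is.character(reference)) reference else bytes_to_text(text_to_bytes(reference))
  n <- nchar(ref, type = "bytes")
  if (n < 1L) stop("reference must be non-empty: nothing can be parsed against it")
  # radix sort is locale-independent (byte order)
  sa <- order(substring(ref, 1:n, n), method = "radix")
  structure(list(ref = ref, n = n, sa = sa), class = "rlz_index")
}

#' @export
print.rlz_index <- function(x, ...) {
  cat(sprintf("RLZ reference index: |R| = %d\n", x$n))
  invisible(x)
}

# Binary search helpers. All comparisons must run under LC_COLLATE=C
# (the caller wraps in withr::with_locale) so `<` and `<=` are byte order.

# first suffix-array slot whose suffix prefix of length nchar(q) is >= q
sa_lower <- function(idx, q) {
  L <- nchar(q)
  lo <- 1L; hi <- idx$n + 1L
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    s <- substr(idx$ref, idx$sa[mid], min(idx$sa[mid] + L - 1L, idx$n))
    if (s < q) lo <- mid + 1L else hi <- mid
  }
  lo
}

# first suffix-array slot whose suffix prefix of length nchar(q) is > q
sa_upper <- function(idx, q, from) {
  L <- nchar(q)
  lo <- from; hi <- idx$n + 1L
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    s <- substr(idx$ref, idx$sa[mid], min(idx$sa[mid] + L - 1L, idx$n))
    if (s <= q) lo <- mid + 1L else hi <- mid
  }
  lo
}

sa_has_prefix <- function(idx, q) {
  lo <- sa_lower(idx, q)
  if (lo > idx$n) return(FALSE)
  L <- nchar(q)
  substr(idx$ref, idx$sa[lo], min(idx$sa[lo] + L - 1L, idx$n)) == q
}

# Longest prefix of `q` occurring in the reference; leftmost position on ties.
# Returns list(len, pos) with pos 0-based (len 0 => no match at all).
sa_longest_match <- function(idx, q) {
  max_l <- min(nchar(q), idx$n)
  if (max_l == 0L || !sa_has_prefix(idx, substr(q, 1L, 1L))) {
    return(list(len = 0L, pos = NA_integer_))
  }
  lo <- 1L; hi <- max_l
  while (lo < hi) {
    mid <- (lo + hi + 1L) %/% 2L
    if (sa_has_prefix(idx, substr(q, 1L, mid))) lo <- mid else hi <- mid - 1L
  }
  qq <- substr(q, 1L, lo)
  a <- sa_lower(idx, qq)
  b <- sa_upper(idx, qq, a)
  list(len = lo, pos = min(idx$sa[a:(b - 1L)]) - 1L)
}

#' RLZ-parse a target against a reference
#'
#' Greedy left-to-right factorization: each phrase is the longest prefix of
#' the remaining target suffix that occurs in the reference (leftmost source
#' position on ties). A target character absent from the reference either
#' becomes a length-1 literal phrase (`policy = "literal"`, the default) or
#' raises an error naming the failing 0-based target position
#' (`policy = "strict"`).
#'
#' @param target character scalar or raw vector, non-empty.
#' @param reference an [rlz_index()] or the reference text itself.
#' @param policy `"literal"` or `"strict"`.
#' @return A data.frame of class `rlz_parse` with one row per phrase and
#'   columns `pos` (0-based source start, `NA` for literals), `len`,
#'   `literal` (logical) and `byte` (literal byte value, `NA` otherwise).
#' @export
rlz_parse <- function(target, reference, policy = c("literal", "strict")) {
  policy <- match.arg(policy)
  idx <- if (inherits(reference, "rlz_index")) reference else rlz_index(reference)
  tgt <- if (is.character(target)) target else bytes_to_text(text_to_bytes(target))
  n_t <- nchar(tgt, type = "bytes")
  if (n_t < 1L) stop("target must be non-empty")
  pos <- integer(0); len <- integer(0); lit <- logical(0); byte <- integer(0)
  withr::with_locale(c(LC_COLLATE = "C"), {
    t0 <- 1L
    while (t0 <= n_t) {
      q <- substr(tgt, t0, min(t0 + idx$n - 1L, n_t))
      m <- sa_longest_match(idx, q)
      if (m$len == 0L) {
        if (policy == "strict") {
          stop(sprintf(
            "strict policy: target position %d holds a character absent from the reference",
            t0 - 1L))
        }
        pos <- c(pos, NA_integer_); len <- c(len, 1L); lit <- c(lit, TRUE)
        byte <- c(byte, text_to_bytes(substr(tgt, t0, t0)))
        t0 <- t0 + 1L
      } else {
        pos <- c(pos, m$pos); len <- c(len, m$len); lit <- c(lit, FALSE)
        byte <- c(byte, NA_integer_)
        t0 <- t0 + m$len
      }
    }
  })
  structure(data.frame(pos = pos, len = len, literal = lit, byte = byte),
            class = c("rlz_parse", "data.frame"))
}

#' Expand an RLZ parse back into the target text
#'
#' @param parse an [rlz_parse()] data.frame (columns `pos`, `len`, `literal`,
#'   `byte`).
#' @param reference the reference text (character scalar or raw vector).
#' @return The reconstructed target as a character scalar.
#' @export
expand_parse <- function(parse, reference) {
  ref <- if (is.character(reference)) reference else bytes_to_text(text_to_bytes(reference))
  n <- nchar(ref, type = "bytes")
  if (nrow(parse) == 0L) return("")
  pieces <- character(nrow(parse))
  for (i in seq_len(nrow(parse))) {
    if (isTRUE(parse$literal[i])) {
      pieces[i] <- bytes_to_text(parse$byte[i])
    } else {
      p <- parse$pos[i]; l <- parse$len[i]
      if (is.na(p) || p < 0L || l < 1L || p + l > n) {
        stop(sprintf("phrase %d: (p=%s, len=%s) out of range for |R| = %d",
                     i, p, l, n))
      }
      pieces[i] <- substr(ref, p + 1L, p + l)
    }
  }
  paste(pieces, collapse = "")
}

#' Summary statistics of an RLZ parse
#'
#' @param parse an [rlz_parse()] data.frame; must be non-empty.
#' @return A one-row data.frame with `num_phrases`, `mean_len` and `sd_len`
#'   (population standard deviation of phrase lengths).
#' @export
parse_stats <- function(parse) {
  if (nrow(parse) == 0L) stop("parse is empty")
  l <- parse$len
  m <- mean(l)
  data.frame(num_phrases = nrow(parse),
             mean_len = m,
             sd_len = sqrt(mean((l - m)^2)))
}
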