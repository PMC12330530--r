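# Grammar model: an SLP-style straight-line program given by a start sequence
# C plus binary rules. Like the classic RePair tools, the output is not strict
# Chomsky normal form: terminal rules are implicit via the id < sigma
# convention and C is a sequence rather than a single start symbol.

#' Construct a grammar object
#'
#' @param sigma alphabet size (number of terminal symbols).
#' @param byte_map integer vector of length `sigma`; byte value of each
#'   terminal id in ascending order.
#' @param rules integer matrix with columns `lhs`, `left`, `right` (0-based
#'   symbol ids), one row per non-terminal in creation order. May have zero
#'   rows.
#' @param start_sequence integer vector of 0-based symbol ids (the compressed
#'   representation C).
#' @return An object of class `rlzrp_grammar`.
#' @export
new_grammar <- function(sigma, byte_map, rules, start_sequence) {
  if (is.null(rules) || length(rules) == 0L) {
    rules <- matrix(integer(0), ncol = 3L)
  }
  rules <- matrix(as.integer(rules), ncol = 3L)
  colnames(rules) <- c("lhs", "left", "right")
  structure(
    list(sigma = as.integer(sigma),
         byte_map = as.integer(byte_map),
         rules = rules,
         start_sequence = as.integer(start_sequence)),
    class = "rlzrp_grammar")
}

#' Validate a grammar
#'
#' Checks every structural invariant: byte map shape, contiguous non-terminal
#' ids starting at `sigma`, one rule per left-hand side, acyclicity
#' (`lhs > left` and `lhs > right`), and id ranges in rules and start
#' sequence. Reports violations; never throws.
#'
#' @param g a grammar (see [new_grammar()]).
#' @return Character vector of violation messages; empty if the grammar is
#'   valid.
#' @export
validate_grammar <- function(g) {
  v <- character(0)
  k <- nrow(g$rules)
  n_sym <- g$sigma + k
  if (length(g$byte_map) != g$sigma) {
    v <- c(v, sprintf("byte_map has %d entries but sigma is %d",
                      length(g$byte_map), g$sigma))
  }
  if (anyDuplicated(g$byte_map)) {
    v <- c(v, "byte_map contains duplicate byte values")
  }
  if (any(g$byte_map < 0L | g$byte_map > 255L)) {
    v <- c(v, "byte_map contains values outside 0..255")
  }
  if (k > 0L) {
    expect_lhs <- g$sigma + seq_len(k) - 1L
    bad <- which(g$rules[, "lhs"] != expect_lhs)
    if (length(bad)) {
      if (anyDuplicated(g$rules[, "lhs"])) {
        v <- c(v, sprintf("duplicate lhs id %d",
                          g$rules[which(duplicated(g$rules[, "lhs"]))[1L], "lhs"]))
      }
      v <- c(v, sprintf(
        "rule %d: lhs id %d breaks the contiguous numbering (expected %d)",
        bad[1L], g$rules[bad[1L], "lhs"], expect_lhs[bad[1L]]))
    }
    ord <- which(g$rules[, "lhs"] <= g$rules[, "left"] |
                   g$rules[, "lhs"] <= g$rules[, "right"])
    for (i in ord) {
      v <- c(v, sprintf("rule %d (lhs %d -> %d %d): lhs must exceed both children",
                        i, g$rules[i, "lhs"], g$rules[i, "left"],
                        g$rules[i, "right"]))
    }
    rng <- which(g$rules[, "left"] < 0L | g$rules[, "left"] >= n_sym |
                   g$rules[, "right"] < 0L | g$rules[, "right"] >= n_sym)
    for (i in rng) {
      v <- c(v, sprintf("rule %d references a symbol id outside 0..%d",
                        i, n_sym - 1L))
    }
  }
  if (length(g$start_sequence) &&
      any(g$start_sequence < 0L | g$start_sequence >= n_sym)) {
    i <- which(g$start_sequence < 0L | g$start_sequence >= n_sym)[1L]
    v <- c(v, sprintf("start sequence position %d holds id %d, outside 0..%d",
                      i, g$start_sequence[i], n_sym - 1L))
  }
  v
}

#' Expand a grammar to the text it generates
#'
#' Fully decompresses the grammar: each start-sequence symbol is expanded
#' through the binary rules down to terminal bytes. Expansion is iterative
#' (explicit stack), so deep grammars do not hit R's recursion limit.
#'
#' @param g a valid grammar.
#' @param as `"character"` (default), `"raw"`, or `"ids"` (0-based terminal
#'   ids).
#' @return The expansion of the start sequence.
#' @export
expand_grammar <- function(g, as = c("character", "raw", "ids")) {
  as <- match.arg(as)
  viol <- validate_grammar(g)
  if (length(viol)) stop("malformed grammar: ", viol[1L])
  sigma <- g$sigma
  k <- nrow(g$rules)
  start <- g$start_sequence
  if (k == 0L) {
    out <- start
  } else {
    left <- g$rules[, "left"]
    right <- g$rules[, "right"]
    # expansion lengths in one ascending pass (children precede parents)
    len <- numeric(sigma + k)
    len[seq_len(sigma)] <- 1
    for (i in seq_len(k)) {
      len[sigma + i] <- len[left[i] + 1L] + len[right[i] + 1L]
    }
    total <- sum(len[start + 1L])
    if (total > .Machine$integer.max) stop("expansion too large")
    out <- integer(total)
    oi <- 0L
    stack <- integer(256L)
    for (s in start) {
      top <- 1L
      stack[1L] <- s
      while (top > 0L) {
        x <- stack[top]
        top <- top - 1L
        while (x >= sigma) {
          # push right child, descend into left: emits in left-to-right order
          top <- top + 1L
          if (top > length(stack)) stack <- c(stack, integer(length(stack)))
          stack[top] <- right[x - sigma + 1L]
          x <- left[x - sigma + 1L]
        }
        oi <- oi + 1L
        out[oi] <- x
      }
    }
  }
  switch(as,
         ids = out,
         raw = as.raw(g$byte_map[out + 1L]),
         character = bytes_to_text(g$byte_map[out + 1L]))
}

#' Grammar size accounting
#'
#' @param g a grammar.
#' @return `|C| + 2 * |rules|`: the symbol count of the start sequence plus
#'   two ids per binary rule.
#' @export
grammar_size <- function(g) length(g$start_sequence) + 2L * nrow(g$rules)

#' Write a grammar in the RLZRP1 plain-text format
#'
#' The format is line oriented (UTF-8, LF):
#' \preformatted{
#' RLZRP1 <sigma> <num_rules> <len_C>
#' t <terminal_id> <byte_value>     (sigma lines)
#' r <lhs> <left> <right>           (num_rules lines, ascending lhs)
#' <len_C space-separated ids>      (final line)
#' }
#'
#' @param g a valid grammar.
#' @param path file path to write.
#' @return `path`, invisibly.
#' @export
write_grammar <- function(g, path) {
  viol <- validate_grammar(g)
  if (length(viol)) stop("refusing to write malformed grammar: ", viol[1L])
  k <- nrow(g$rules)
  lines <- c(
    sprintf("RLZRP1 %d %d %d", g$sigma, k, length(g$start_sequence)),
    sprintf("t %d %d", seq_len(g$sigma) - 1L, g$byte_map),
    if (k > 0L) sprintf("r %d %d %d", g$rules[, "lhs"], g$rules[, "left"],
                        g$rules[, "right"]),
    paste(g$start_sequence, collapse = " "))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con = con, sep = "\n")
  invisible(path)
}

#' Read a grammar from an RLZRP1 file
#'
#' @param path file path.
#' @return A grammar object; errors (with the offending line number) on
#'   syntax problems, id range violations, or count mismatches. No partial
#'   grammar is ever returned.
#' @export
read_grammar <- function(path) {
  lines <- readLines(path, warn = FALSE)
  fail <- function(ln, msg) stop(sprintf("%s: line %d: %s", path, ln, msg))
  if (length(lines) < 1L) fail(1L, "empty file")
  hdr <- strsplit(lines[1L], " ", fixed = TRUE)[[1L]]
  if (length(hdr) != 4L || hdr[1L] != "RLZRP1") {
    fail(1L, "expected header 'RLZRP1 <sigma> <num_rules> <len_C>'")
  }
  sigma <- suppressWarnings(as.integer(hdr[2L]))
  k <- suppressWarnings(as.integer(hdr[3L]))
  len_c <- suppressWarnings(as.integer(hdr[4L]))
  if (anyNA(c(sigma, k, len_c)) || sigma < 0L || k < 0L || len_c < 0L) {
    fail(1L, "header counts must be non-negative integers")
  }
  need <- 1L + sigma + k + 1L
  if (length(lines) < need) {
    fail(length(lines), sprintf("truncated file: expected %d lines", need))
  }
  byte_map <- integer(sigma)
  for (i in seq_len(sigma)) {
    ln <- 1L + i
    f <- strsplit(lines[ln], " ", fixed = TRUE)[[1L]]
    if (length(f) != 3L || f[1L] != "t") fail(ln, "expected 't <id> <byte>'")
    id <- suppressWarnings(as.integer(f[2L]))
    bv <- suppressWarnings(as.integer(f[3L]))
    if (is.na(id) || id != i - 1L) fail(ln, "terminal ids must be 0,1,2,...")
    if (is.na(bv) || bv < 0L || bv > 255L) fail(ln, "byte value outside 0..255")
    byte_map[i] <- bv
  }
  rules <- matrix(integer(0), ncol = 3L)
  if (k > 0L) {
    rules <- matrix(0L, nrow = k, ncol = 3L)
    for (i in seq_len(k)) {
      ln <- 1L + sigma + i
      f <- strsplit(lines[ln], " ", fixed = TRUE)[[1L]]
      if (length(f) != 4L || f[1L] != "r") {
        fail(ln, "expected 'r <lhs> <left> <right>'")
      }
      ids <- suppressWarnings(as.integer(f[2:4]))
      if (anyNA(ids)) fail(ln, "rule ids must be integers")
      if (ids[1L] != sigma + i - 1L) {
        fail(ln, sprintf("lhs %d out of order (expected %d)", ids[1L],
                         sigma + i - 1L))
      }
      if (any(ids[2:3] < 0L) || any(ids[2:3] >= sigma + k)) {
        fail(ln, sprintf("rule child id outside 0..%d", sigma + k - 1L))
      }
      rules[i, ] <- ids
    }
  }
  ln <- 1L + sigma + k + 1L
  cs <- lines[ln]
  start <- if (nzchar(cs)) {
    suppressWarnings(as.integer(strsplit(cs, " ", fixed = TRUE)[[1L]]))
  } else integer(0)
  if (anyNA(start)) fail(ln, "start sequence contains a non-integer token")
  if (length(start) != len_c) {
    fail(ln, sprintf("start sequence has %d symbols but header declares %d",
                     length(start), len_c))
  }
  if (length(start) && any(start < 0L | start >= sigma + k)) {
    fail(ln, sprintf("start sequence id outside 0..%d", sigma + k - 1L))
  }
  g <- new_grammar(sigma, byte_map, rules, start)
  viol <- validate_grammar(g)
  if (length(viol)) fail(ln, paste("invalid grammar:", viol[1L]))
  g
}

#' @export
print.rlzrp_grammar <- function(x, ...) {
  cat(sprintf(
    "RLZ-RePair grammar: sigma = %d, rules = %d, |C| = %d (size %d)\n",
    x$sigma, nrow(x$rules), length(x$start_sequence), grammar_size(x)))
  invisible(x)
}
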