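# The full compression loop: pick the most frequent bigram, make boundary
# characters explicit until no phrase can be invalidated, substitute in the
# reference and the explicit phrases, record the rule, repeat until no
# bigram occurs more than once.

# first phrase-boundary occurrence of (a,b), as the left phrase id, or 0
find_phrase_boundary <- function(st, a, b) {
  id <- st$ph_head
  while (id != 0L) {
    nid <- st$ph_next[id]
    if (nid != 0L && ph_last_sym(st, id) == a && ph_first_sym(st, nid) == b) {
      return(id)
    }
    id <- nid
  }
  0L
}

# first reference occurrence of (a,b) with a partial phrase overlap, as the
# absolute left cell, or 0
find_source_boundary <- function(st, a, b) {
  c1 <- st$ref_head
  while (c1 != 0L) {
    c2 <- st$ref_next[c1]
    if (c2 == 0L) break
    if (st$ref_sym[c1] == a && st$ref_sym[c2] == b) {
      part <- stab_partial(st, c1, c2)
      if (length(part$end_side) || length(part$start_side)) return(c1)
    }
    c1 <- c2
  }
  0L
}

# resolve every boundary condition for (a,b); resolutions can cascade (a
# shrunk interval may expose a new overlap, an extracted character a new
# boundary bigram), so iterate to a fixed point. Each step moves at least
# one character from non-explicit to explicit storage, so this terminates.
resolve_all_boundaries <- function(st, a, b) {
  steps <- 0L
  repeat {
    changed <- FALSE
    repeat {
      pid <- find_phrase_boundary(st, a, b)
      if (pid == 0L) break
      resolve_phrase_boundary_id(st, c(a, b), pid)
      changed <- TRUE
      steps <- steps + 1L
    }
    repeat {
      c1 <- find_source_boundary(st, a, b)
      if (c1 == 0L) break
      resolve_source_boundary(st, c(a, b), c1 - 1L)
      changed <- TRUE
      steps <- steps + 1L
    }
    if (!changed) break
  }
  steps
}

debug_recount <- function(st, label) {
  want <- bigram_counts(materialize(st))
  have <- bigram_table(st)
  have_v <- have$count
  names(have_v) <- bt_key(have$a, have$b)
  have_v <- have_v[have_v > 0L]
  ok <- length(want) == length(have_v) &&
    setequal(names(want), names(have_v)) &&
    all(want[names(have_v)] == have_v)
  if (!ok) {
    stop(sprintf(
      "internal error (%s): maintained bigram counts diverge from brute force\nmaintained: %s\nbrute force: %s",
      label,
      paste(sprintf("%s=%d", names(have_v), have_v), collapse = " "),
      paste(sprintf("%s=%d", names(want), want), collapse = " ")))
  }
  invisible(TRUE)
}

# one selection + resolution + substitution round; NULL when finished
engine_round <- function(st) {
  x <- peek_max_bigram(st)
  if (is.null(x)) return(NULL)
  a <- x[1L]; b <- x[2L]
  freq <- st$bt_count[st$bt_pair2slot[[bt_key(a, b)]]]
  res <- resolve_all_boundaries(st, a, b)
  z <- st$next_id
  st$rules <- rbind(st$rules, c(z, a, b))
  st$next_id <- z + 1L
  ref <- substitute_in_reference(st, c(a, b), z)
  em <- substitute_in_explicit(st, c(a, b), z)
  slot <- st$bt_pair2slot[[bt_key(a, b)]]
  if (st$bt_count[slot] != 0L) {
    stop(sprintf(
      "internal error: bigram (%d,%d) still has count %d after substitution",
      a, b, st$bt_count[slot]))
  }
  if (st$debug) debug_recount(st, sprintf("after rule %d -> (%d,%d)", z, a, b))
  list(new_symbol = z, a = a, b = b, freq = freq, resolutions = res,
       ref_merges = ref$merges, explicit_merges = em,
       logical_replacements = ref$logical + em)
}

#' Compress a target against a reference into a RePair grammar
#'
#' Runs the complete pipeline: RLZ-parse the target against the reference,
#' load the parse as phrase intervals over a linked-list reference, compute
#' bigram frequencies once, then repeatedly replace the most frequent bigram
#' with a fresh non-terminal — resolving phrase and source boundary
#' conditions first, so that one physical merge in the reference substitutes
#' every logical occurrence the covering phrases stand for — until no bigram
#' occurs more than once. The resulting grammar is structurally the RePair
#' grammar of the target under the shared tie policy.
#'
#' @param target target text (character scalar or raw vector), non-empty.
#' @param reference reference text, non-empty.
#' @param policy RLZ policy for characters absent from the reference:
#'   `"literal"` (default; they seed one-symbol explicit phrases) or
#'   `"strict"` (error).
#' @param tie_policy frequency tie-break; see [intervals_from_pairs()].
#' @param debug_recount re-verify all counts by brute force after every
#'   round (slow; for testing).
#' @param max_rounds optional cap on replacement rounds.
#' @return An object of class `rlzrp_result`: a list with `grammar` (the
#'   [new_grammar()] object), `parse` (the RLZ parse), `stats` (one row per
#'   round: chosen bigram, its frequency, boundary resolutions, physical
#'   reference merges, explicit merges, logical replacements) and `state`
#'   (the final engine state).
#' @export
rlz_repair <- function(target, reference, policy = c("literal", "strict"),
                       tie_policy = c("lex", "insertion", "lra"),
                       debug_recount = FALSE, max_rounds = Inf) {
  policy <- match.arg(policy)
  tie_policy <- match.arg(tie_policy)
  idx <- rlz_index(reference)
  parse <- rlz_parse(target, idx, policy)
  st <- intervals_from_pairs(parse, reference, tie_policy, debug_recount)
  init_frequencies(st)
  rounds <- list()
  r <- 0L
  while (r < max_rounds) {
    info <- engine_round(st)
    if (is.null(info)) break
    r <- r + 1L
    rounds[[r]] <- info
  }
  start <- materialize(st)
  grammar <- new_grammar(st$sigma, st$alpha$byte_map, st$rules, start)
  stats <- if (r > 0L) {
    data.frame(
      round = seq_len(r),
      new_symbol = vapply(rounds, `[[`, integer(1), "new_symbol"),
      a = vapply(rounds, `[[`, integer(1), "a"),
      b = vapply(rounds, `[[`, integer(1), "b"),
      freq = vapply(rounds, `[[`, integer(1), "freq"),
      resolutions = vapply(rounds, `[[`, integer(1), "resolutions"),
      ref_merges = vapply(rounds, `[[`, integer(1), "ref_merges"),
      explicit_merges = vapply(rounds, `[[`, integer(1), "explicit_merges"),
      logical_replacements = vapply(rounds, `[[`, integer(1),
                                    "logical_replacements"))
  } else {
    data.frame(round = integer(0), new_symbol = integer(0), a = integer(0),
               b = integer(0), freq = integer(0), resolutions = integer(0),
               ref_merges = integer(0), explicit_merges = integer(0),
               logical_replacements = integer(0))
  }
  structure(list(grammar = grammar, parse = parse, stats = stats, state = st),
            class = "rlzrp_result")
}

#' @export
print.rlzrp_result <- function(x, ...) {
  phys <- sum(x$stats$ref_merges) + sum(x$stats$explicit_merges)
  logi <- sum(x$stats$logical_replacements)
  cat(sprintf(
    "RLZ-RePair result: %d rounds, %d rules, |C| = %d\n",
    nrow(x$stats), nrow(x$grammar$rules), length(x$grammar$start_sequence)))
  cat(sprintf(
    "  physical merges: %d (reference %d, explicit %d); logical replacements: %d; saved: %d\n",
    phys, sum(x$stats$ref_merges), sum(x$stats$explicit_merges), logi,
    logi - phys))
  invisible(x)
}

#' Compression driver returning just the grammar
#'
#' Convenience wrapper around [rlz_repair()] for callers that only need the
#' grammar object.
#'
#' @inheritParams rlz_repair
#' @return A grammar object (see [new_grammar()]).
#' @export
run_compression <- function(target, reference,
                            policy = c("literal", "strict"),
                            tie_policy = c("lex", "insertion", "lra"),
                            debug_recount = FALSE) {
  rlz_repair(target, reference, policy = policy, tie_policy = tie_policy,
             debug_recount = debug_recount)$grammar
}
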