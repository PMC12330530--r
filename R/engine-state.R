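# Engine state for the RLZ-RePair loop.
#
# The reference lives as a doubly linked list embedded in an array: merging a
# bigram rewrites the left cell and unlinks the right one, so the absolute
# indices of surviving cells never move and phrase intervals keep their
# meaning. Phrases form a doubly linked chain of non-explicit intervals
# (s, e) into the reference and explicit literal runs; the bigram table maps
# each bigram of the working sequence to its current frequency.
#
# All mutable fields live in one environment of class `rlzrp_state`.

#' Build an engine state from an RLZ parse
#'
#' Reinterprets each (p, len) pair as the inclusive reference interval
#' `(s, e) = (p, p + len - 1)` it spans (a non-explicit phrase); literal
#' pairs become explicit one-symbol phrases (adjacent literals are merged
#' into a single explicit run). The reference is loaded as a linked list and
#' the phrase chain is assembled in parse order. Frequencies are *not*
#' computed here; call [init_frequencies()] next.
#'
#' @param parse an [rlz_parse()] data.frame.
#' @param reference the reference text (character scalar or raw vector).
#' @param tie_policy how [peek_max_bigram()] breaks frequency ties:
#'   `"lex"` (smallest (left, right) id pair; fully state-determined, the
#'   default), `"insertion"` (first bigram ever entered into the table), or
#'   `"lra"` (least recently accessed, where an access is a count update or a
#'   peek, with insertion as the initial access).
#' @param debug if `TRUE`, the engine re-counts bigrams by brute force after
#'   every substitution round and aborts on any mismatch.
#' @return An environment of class `rlzrp_state`.
#' @export
intervals_from_pairs <- function(parse, reference,
                                 tie_policy = c("lex", "insertion", "lra"),
                                 debug = FALSE) {
  tie_policy <- match.arg(tie_policy)
  ref_txt <- if (is.character(reference)) reference else bytes_to_text(text_to_bytes(reference))
  lit_bytes <- parse$byte[parse$literal]
  alpha <- if (length(lit_bytes)) {
    alphabet_over(ref_txt, as.integer(lit_bytes))
  } else {
    alphabet_over(ref_txt)
  }
  n <- nchar(ref_txt, type = "bytes")
  st <- new.env(parent = emptyenv())
  class(st) <- "rlzrp_state"
  st$alpha <- alpha
  st$sigma <- alpha$sigma
  st$next_id <- alpha$sigma
  st$tie_policy <- tie_policy
  st$debug <- debug
  # linked reference (1-based cells internally)
  st$ref_sym <- encode_ids(ref_txt, alpha)
  st$ref_prev <- c(0L, seq_len(n - 1L))
  st$ref_next <- c(seq_len(n - 1L) + 1L, 0L)
  st$ref_alive <- rep(TRUE, n)
  st$ref_head <- 1L
  st$ref_n <- n
  # phrase chain
  st$ph_type <- integer(0)   # 0 dead, 1 non-explicit, 2 explicit
  st$ph_s <- integer(0)      # 1-based cell index of first cell
  st$ph_e <- integer(0)      # 1-based cell index of last cell
  st$ph_syms <- list()       # explicit content (0-based symbol ids)
  st$ph_prev <- integer(0)
  st$ph_next <- integer(0)
  st$ph_head <- 0L
  st$ph_tail <- 0L
  # bigram table
  st$bt_pair2slot <- new.env(parent = emptyenv())
  st$bt_a <- integer(0)
  st$bt_b <- integer(0)
  st$bt_count <- integer(0)
  st$bt_stamp <- numeric(0)
  st$bt_clock <- 0
  # grammar under construction + per-round statistics
  st$rules <- matrix(integer(0), ncol = 3L,
                     dimnames = list(NULL, c("lhs", "left", "right")))
  st$stats <- list()
  for (i in seq_len(nrow(parse))) {
    if (isTRUE(parse$literal[i])) {
      ph_append_explicit(st, alpha$byte2id[parse$byte[i] + 1L])
    } else {
      p <- parse$pos[i]; l <- parse$len[i]
      if (is.na(p) || p < 0L || l < 1L || p + l > n) {
        stop(sprintf("phrase %d: (p=%s, len=%s) outside reference of length %d",
                     i, p, l, n))
      }
      ph_append_nonexplicit(st, p + 1L, p + l)
    }
  }
  st
}

#' @export
print.rlzrp_state <- function(x, ...) {
  ids <- chain_ids(x)
  cat(sprintf(
    "RLZ-RePair engine state: |R| = %d cells (%d alive), %d phrases (%d explicit), next id %d\n",
    x$ref_n, sum(x$ref_alive), length(ids), sum(x$ph_type[ids] == 2L), x$next_id))
  invisible(x)
}

# ---- phrase chain primitives -------------------------------------------

ph_alloc <- function(st) {
  id <- length(st$ph_type) + 1L
  st$ph_type[id] <- 0L
  st$ph_s[id] <- 0L
  st$ph_e[id] <- 0L
  st$ph_syms[[id]] <- integer(0)
  st$ph_prev[id] <- 0L
  st$ph_next[id] <- 0L
  id
}

ph_link_tail <- function(st, id) {
  if (st$ph_tail == 0L) {
    st$ph_head <- id
    st$ph_tail <- id
  } else {
    st$ph_next[st$ph_tail] <- id
    st$ph_prev[id] <- st$ph_tail
    st$ph_tail <- id
  }
}

ph_append_nonexplicit <- function(st, s, e) {
  id <- ph_alloc(st)
  st$ph_type[id] <- 1L
  st$ph_s[id] <- s
  st$ph_e[id] <- e
  ph_link_tail(st, id)
  id
}

ph_append_explicit <- function(st, syms) {
  # merge into a trailing explicit phrase to keep the no-adjacent-explicits
  # invariant
  if (st$ph_tail != 0L && st$ph_type[st$ph_tail] == 2L) {
    st$ph_syms[[st$ph_tail]] <- c(st$ph_syms[[st$ph_tail]], syms)
    return(st$ph_tail)
  }
  id <- ph_alloc(st)
  st$ph_type[id] <- 2L
  st$ph_syms[[id]] <- as.integer(syms)
  ph_link_tail(st, id)
  id
}

# insert phrase `id` immediately after `after` (0 = at head)
ph_insert_after <- function(st, after, id) {
  if (after == 0L) {
    nxt <- st$ph_head
    st$ph_prev[id] <- 0L
    st$ph_next[id] <- nxt
    if (nxt != 0L) st$ph_prev[nxt] <- id else st$ph_tail <- id
    st$ph_head <- id
  } else {
    nxt <- st$ph_next[after]
    st$ph_next[after] <- id
    st$ph_prev[id] <- after
    st$ph_next[id] <- nxt
    if (nxt != 0L) st$ph_prev[nxt] <- id else st$ph_tail <- id
  }
}

ph_delete <- function(st, id) {
  p <- st$ph_prev[id]; n <- st$ph_next[id]
  if (p != 0L) st$ph_next[p] <- n else st$ph_head <- n
  if (n != 0L) st$ph_prev[n] <- p else st$ph_tail <- p
  st$ph_type[id] <- 0L
  st$ph_syms[[id]] <- integer(0)
  # merge explicit neighbours that became adjacent (text unchanged)
  if (p != 0L && n != 0L && st$ph_type[p] == 2L && st$ph_type[n] == 2L) {
    st$ph_syms[[p]] <- c(st$ph_syms[[p]], st$ph_syms[[n]])
    nn <- st$ph_next[n]
    st$ph_next[p] <- nn
    if (nn != 0L) st$ph_prev[nn] <- p else st$ph_tail <- p
    st$ph_type[n] <- 0L
    st$ph_syms[[n]] <- integer(0)
  }
  invisible(NULL)
}

chain_ids <- function(st) {
  out <- integer(0)
  id <- st$ph_head
  while (id != 0L) {
    out <- c(out, id)
    id <- st$ph_next[id]
  }
  out
}

# first/last symbol a phrase contributes to the working sequence
ph_first_sym <- function(st, id) {
  if (st$ph_type[id] == 2L) st$ph_syms[[id]][1L] else st$ref_sym[st$ph_s[id]]
}

ph_last_sym <- function(st, id) {
  if (st$ph_type[id] == 2L) {
    s <- st$ph_syms[[id]]
    s[length(s)]
  } else {
    st$ref_sym[st$ph_e[id]]
  }
}

# symbols of a non-explicit phrase by walking the live chain s..e
ph_ref_syms <- function(st, id) {
  s <- st$ph_s[id]; e <- st$ph_e[id]
  if (!st$ref_alive[s] || !st$ref_alive[e]) {
    stop("internal error: phrase endpoint points at a dead reference cell")
  }
  out <- integer(0)
  c1 <- s
  repeat {
    out <- c(out, st$ref_sym[c1])
    if (c1 == e) break
    c1 <- st$ref_next[c1]
    if (c1 == 0L) stop("internal error: phrase end unreachable from start")
  }
  out
}

#' Materialize the working sequence
#'
#' Concatenates the expansion of every phrase in chain order: the logical
#' reference symbols `s..e` for non-explicit phrases and the stored symbols
#' for explicit ones. This is the current working representation of the
#' target; it is unchanged by boundary resolutions and shrinks only at
#' substitutions.
#'
#' @param state an engine state.
#' @return Integer vector of 0-based symbol ids.
#' @export
materialize <- function(state) {
  ids <- chain_ids(state)
  if (length(ids) == 0L) return(integer(0))
  parts <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    id <- ids[i]
    parts[[i]] <- if (state$ph_type[id] == 2L) state$ph_syms[[id]] else ph_ref_syms(state, id)
  }
  unlist(parts, use.names = FALSE)
}

#' View the phrase chain as a table
#'
#' @param state an engine state.
#' @return A data.frame in chain order with columns `type`
#'   (`"non_explicit"`/`"explicit"`), `s`, `e` (0-based inclusive reference
#'   interval, `NA` for explicit phrases) and `n_syms`.
#' @export
phrase_intervals <- function(state) {
  ids <- chain_ids(state)
  tp <- state$ph_type[ids]
  data.frame(
    type = ifelse(tp == 2L, "explicit", "non_explicit"),
    s = ifelse(tp == 2L, NA_integer_, state$ph_s[ids] - 1L),
    e = ifelse(tp == 2L, NA_integer_, state$ph_e[ids] - 1L),
    n_syms = vapply(ids, function(id) {
      if (state$ph_type[id] == 2L) length(state$ph_syms[[id]])
      else length(ph_ref_syms(state, id))
    }, integer(1)))
}

# ---- bigram table primitives -------------------------------------------

bt_key <- function(a, b) paste0(a, "_", b)

bt_slot <- function(st, a, b) {
  key <- bt_key(a, b)
  slot <- st$bt_pair2slot[[key]]
  if (is.null(slot)) {
    slot <- length(st$bt_a) + 1L
    st$bt_a[slot] <- a
    st$bt_b[slot] <- b
    st$bt_count[slot] <- 0L
    st$bt_clock <- st$bt_clock + 1
    st$bt_stamp[slot] <- st$bt_clock
    st$bt_pair2slot[[key]] <- slot
  }
  slot
}

# count update; an update counts as an access under the "lra" policy
bt_bump <- function(st, a, b, d) {
  if (is.na(a) || is.na(b)) return(invisible(NULL))
  slot <- bt_slot(st, a, b)
  nc <- st$bt_count[slot] + as.integer(d)
  if (nc < 0L) {
    stop(sprintf("internal error: bigram (%d,%d) count went negative", a, b))
  }
  st$bt_count[slot] <- nc
  if (st$tie_policy == "lra") {
    st$bt_clock <- st$bt_clock + 1
    st$bt_stamp[slot] <- st$bt_clock
  }
  invisible(NULL)
}

#' Current bigram counts as a table
#'
#' @param state an engine state.
#' @param drop_zero drop bigrams whose count fell to zero (default `TRUE`).
#' @return A data.frame with columns `a`, `b` (0-based symbol ids) and
#'   `count`.
#' @export
bigram_table <- function(state, drop_zero = TRUE) {
  keep <- if (drop_zero) state$bt_count > 0L else rep(TRUE, length(state$bt_count))
  data.frame(a = state$bt_a[keep], b = state$bt_b[keep],
             count = state$bt_count[keep])
}

#' Initialize bigram frequencies from the phrase structure
#'
#' Computes every bigram count of the working sequence once, summing bigrams
#' within phrases and those crossing phrase boundaries (the total mass is one
#' less than the length of the target). Performed a single time before the
#' replacement loop; thereafter counts are maintained incrementally.
#'
#' @param state a fresh engine state from [intervals_from_pairs()].
#' @return The bigram table (see [bigram_table()]), invisibly.
#' @export
init_frequencies <- function(state) {
  state$bt_pair2slot <- new.env(parent = emptyenv())
  state$bt_a <- integer(0)
  state$bt_b <- integer(0)
  state$bt_count <- integer(0)
  state$bt_stamp <- numeric(0)
  state$bt_clock <- 0
  ids <- chain_ids(state)
  prev_last <- NA_integer_
  for (id in ids) {
    syms <- if (state$ph_type[id] == 2L) state$ph_syms[[id]] else ph_ref_syms(state, id)
    if (!is.na(prev_last)) bt_bump(state, prev_last, syms[1L], 1L)
    if (length(syms) > 1L) {
      for (i in seq_len(length(syms) - 1L)) {
        bt_bump(state, syms[i], syms[i + 1L], 1L)
      }
    }
    prev_last <- syms[length(syms)]
  }
  invisible(bigram_table(state))
}

#' Most frequent bigram, or NULL when done
#'
#' Returns a maximal-frequency bigram of the working sequence, breaking ties
#' by the state's tie policy, or `NULL` when no bigram occurs more than once
#' (the RePair termination condition).
#'
#' @param state an engine state with initialized frequencies.
#' @return Integer vector `c(a, b)` of 0-based symbol ids, or `NULL`.
#' @export
peek_max_bigram <- function(state) {
  if (length(state$bt_count) == 0L) return(NULL)
  m <- max(state$bt_count)
  if (m < 2L) return(NULL)
  cand <- which(state$bt_count == m)
  pick <- switch(state$tie_policy,
    lex = cand[order(state$bt_a[cand], state$bt_b[cand])][1L],
    insertion = cand[1L],  # slots are allocated in first-seen order
    lra = cand[which.min(state$bt_stamp[cand])])
  if (state$tie_policy == "lra") {
    state$bt_clock <- state$bt_clock + 1
    state$bt_stamp[pick] <- state$bt_clock
  }
  c(state$bt_a[pick], state$bt_b[pick])
}
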