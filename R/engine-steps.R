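# Step operations of the RLZ-RePair engine: occurrence classification,
# boundary resolution (which never changes the working sequence), and bigram
# substitution in the reference and in explicit phrases.

# ---- occurrence scanning ------------------------------------------------

# all logical occurrences of (a,b) in the live reference, as a 2-column
# matrix of absolute cell indices (left, right); overlapping occurrences in
# runs are all listed
ref_occurrences <- function(st, a, b) {
  out_l <- integer(0); out_r <- integer(0)
  c1 <- st$ref_head
  while (c1 != 0L) {
    c2 <- st$ref_next[c1]
    if (c2 == 0L) break
    if (st$ref_sym[c1] == a && st$ref_sym[c2] == b) {
      out_l <- c(out_l, c1); out_r <- c(out_r, c2)
    }
    c1 <- c2
  }
  cbind(left = out_l, right = out_r)
}

# phrases fully covering cells (c1, c2): the interval-stab query
stab_covering <- function(st, c1, c2) {
  which(st$ph_type == 1L & st$ph_s <= c1 & st$ph_e >= c2)
}

# phrases overlapping exactly one cell of the occurrence (c1, c2)
stab_partial <- function(st, c1, c2) {
  list(end_side = which(st$ph_type == 1L & st$ph_e == c1),
       start_side = which(st$ph_type == 1L & st$ph_s == c2))
}

#' Classify every occurrence of a bigram in the working sequence
#'
#' Occurrences fall into four groups: `interior` (a reference occurrence
#' fully covered by at least one non-explicit phrase), `source_boundary`
#' (a reference occurrence overlapping exactly one endpoint cell of some
#' phrase interval), `phrase_boundary` (an occurrence spanning two
#' consecutive phrases of the chain), and `explicit` (inside one explicit
#' phrase). A single reference occurrence can be interior with respect to
#' one phrase and a source-boundary for another; both roles are reported.
#'
#' @param state an engine state.
#' @param bigram integer `c(a, b)` of 0-based symbol ids.
#' @return A list with components `interior` (list of `cells` (0-based
#'   reference cell pair) + `phrases` (chain positions of covering
#'   phrases)), `source_boundary` (`cells`, `phrase` chain position,
#'   `side` `"start"`/`"end"`), `phrase_boundary` (`left`, `right` chain
#'   positions), and `explicit` (`phrase` chain position, `offset` 0-based
#'   within the explicit run).
#' @export
classify_occurrences <- function(state, bigram) {
  a <- bigram[1L]; b <- bigram[2L]
  cids <- chain_ids(state)
  cpos <- integer(length(state$ph_type))
  cpos[cids] <- seq_along(cids)
  interior <- list(); source_boundary <- list()
  occ <- ref_occurrences(state, a, b)
  if (nrow(occ)) {
    for (i in seq_len(nrow(occ))) {
      c1 <- unname(occ[i, 1L]); c2 <- unname(occ[i, 2L])
      cov <- stab_covering(state, c1, c2)
      if (length(cov)) {
        interior[[length(interior) + 1L]] <-
          list(cells = c(c1, c2) - 1L, phrases = sort(cpos[cov]))
      }
      part <- stab_partial(state, c1, c2)
      for (p in part$end_side) {
        source_boundary[[length(source_boundary) + 1L]] <-
          list(cells = c(c1, c2) - 1L, phrase = cpos[p], side = "end")
      }
      for (p in part$start_side) {
        source_boundary[[length(source_boundary) + 1L]] <-
          list(cells = c(c1, c2) - 1L, phrase = cpos[p], side = "start")
      }
    }
  }
  phrase_boundary <- list()
  for (i in seq_along(cids)) {
    id <- cids[i]
    nid <- state$ph_next[id]
    if (nid != 0L && ph_last_sym(state, id) == a &&
        ph_first_sym(state, nid) == b) {
      phrase_boundary[[length(phrase_boundary) + 1L]] <-
        list(left = i, right = i + 1L)
    }
  }
  explicit <- list()
  for (i in seq_along(cids)) {
    id <- cids[i]
    if (state$ph_type[id] != 2L) next
    v <- state$ph_syms[[id]]
    if (length(v) < 2L) next
    hit <- which(v[-length(v)] == a & v[-1L] == b)
    for (off in hit) {
      explicit[[length(explicit) + 1L]] <- list(phrase = i, offset = off - 1L)
    }
  }
  list(interior = interior, source_boundary = source_boundary,
       phrase_boundary = phrase_boundary, explicit = explicit)
}

# ---- boundary resolution ------------------------------------------------

# explicit phrase immediately left of `id` (created empty if absent)
explicit_left_of <- function(st, id) {
  q <- st$ph_prev[id]
  if (q != 0L && st$ph_type[q] == 2L) return(q)
  e <- ph_alloc(st)
  st$ph_type[e] <- 2L
  ph_insert_after(st, q, e)
  e
}

explicit_right_of <- function(st, id) {
  q <- st$ph_next[id]
  if (q != 0L && st$ph_type[q] == 2L) return(q)
  e <- ph_alloc(st)
  st$ph_type[e] <- 2L
  ph_insert_after(st, id, e)
  e
}

# drop the first character of non-explicit phrase `id` into the explicit
# phrase to its left (appended at its end); deletes the phrase if emptied
shrink_start <- function(st, id) {
  s <- st$ph_s[id]
  ch <- st$ref_sym[s]
  e <- explicit_left_of(st, id)
  st$ph_syms[[e]] <- c(st$ph_syms[[e]], ch)
  if (st$ph_e[id] == s) ph_delete(st, id) else st$ph_s[id] <- st$ref_next[s]
  invisible(NULL)
}

# drop the last character into the explicit phrase to the right (prepended)
shrink_end <- function(st, id) {
  en <- st$ph_e[id]
  ch <- st$ref_sym[en]
  e <- explicit_right_of(st, id)
  st$ph_syms[[e]] <- c(ch, st$ph_syms[[e]])
  if (st$ph_s[id] == en) ph_delete(st, id) else st$ph_e[id] <- st$ref_prev[en]
  invisible(NULL)
}

#' Resolve a phrase boundary condition
#'
#' When the chosen bigram spans two consecutive phrases, its two characters
#' are made explicit: both characters move into an explicit phrase between
#' two non-explicit phrases, or the single non-explicit participant loses
#' one boundary character into the adjacent explicit phrase. The working
#' sequence is unchanged; emptied phrases are removed and adjacent explicit
#' phrases merged. An occurrence that is not actually at the named boundary
#' is rejected as a no-op.
#'
#' @param state an engine state.
#' @param bigram integer `c(a, b)`.
#' @param occurrence chain position (1-based, as reported by
#'   [classify_occurrences()]) of the left phrase of the boundary.
#' @return `TRUE` if a resolution was applied, `FALSE` for a no-op,
#'   invisibly.
#' @export
resolve_phrase_boundary <- function(state, bigram, occurrence) {
  cids <- chain_ids(state)
  if (occurrence < 1L || occurrence > length(cids)) return(invisible(FALSE))
  invisible(resolve_phrase_boundary_id(state, bigram, cids[occurrence]))
}

resolve_phrase_boundary_id <- function(st, bigram, p_id) {
  q_id <- st$ph_next[p_id]
  if (q_id == 0L) return(FALSE)
  if (ph_last_sym(st, p_id) != bigram[1L] ||
      ph_first_sym(st, q_id) != bigram[2L]) {
    return(FALSE)
  }
  tp <- st$ph_type[p_id]; tq <- st$ph_type[q_id]
  if (tp == 1L && tq == 1L) {
    e <- ph_alloc(st)
    st$ph_type[e] <- 2L
    ph_insert_after(st, p_id, e)
    shrink_end(st, p_id)    # prepends a to e
    shrink_start(st, q_id)  # appends b to e
  } else if (tp == 1L && tq == 2L) {
    shrink_end(st, p_id)    # a joins the beginning of the explicit phrase
  } else if (tp == 2L && tq == 1L) {
    shrink_start(st, q_id)  # b joins the end of the explicit phrase
  } else {
    return(FALSE)           # two adjacent explicits cannot exist
  }
  TRUE
}

#' Resolve a source boundary condition
#'
#' For a reference occurrence of the chosen bigram at cells `(j, j+1)`,
#' every non-explicit phrase overlapping exactly one of the two cells has
#' its overlapping boundary character copied out as a literal (to the end
#' of the explicit phrase on its left for start overlaps, to the start of
#' the explicit phrase on its right for end overlaps) and its interval
#' shrunk by one. Phrases shrunk past zero length are removed. The working
#' sequence is unchanged. If no phrase overlaps the occurrence, the state
#' is untouched.
#'
#' @param state an engine state.
#' @param bigram integer `c(a, b)`.
#' @param occurrence 0-based absolute reference cell index of the left cell
#'   of the occurrence.
#' @return Number of phrase boundary characters made explicit, invisibly.
#' @export
resolve_source_boundary <- function(state, bigram, occurrence) {
  c1 <- as.integer(occurrence) + 1L
  if (c1 < 1L || c1 > state$ref_n || !state$ref_alive[c1]) {
    return(invisible(0L))
  }
  c2 <- state$ref_next[c1]
  if (c2 == 0L || state$ref_sym[c1] != bigram[1L] ||
      state$ref_sym[c2] != bigram[2L]) {
    return(invisible(0L))
  }
  part <- stab_partial(state, c1, c2)
  moved <- 0L
  for (p in part$start_side) {   # phrase starts at j+1: T[s] participates
    shrink_start(state, p)
    moved <- moved + 1L
  }
  for (p in part$end_side) {     # phrase ends at j: T[e] participates
    shrink_end(state, p)
    moved <- moved + 1L
  }
  invisible(moved)
}

# ---- substitution -------------------------------------------------------

#' Substitute a bigram inside the reference
#'
#' Scans the live reference left to right and merges every occurrence of the
#' bigram that is fully covered by at least one non-explicit phrase: the left
#' cell takes the new symbol, the right cell is unlinked, and any phrase
#' endpoint at the dead cell is remapped to the surviving cell. Overlapping
#' occurrences in runs are taken leftmost-first. Frequency updates are
#' applied once per covering phrase (each covering phrase is one logical
#' occurrence in the target), consulting the boundary character of the
#' adjacent chain phrase when the occurrence touches a phrase edge.
#' Occurrences covered by no phrase contribute nothing to the target and are
#' skipped. Remaining partial overlaps indicate unresolved source boundaries
#' and raise an internal-consistency error.
#'
#' @param state an engine state.
#' @param bigram integer `c(a, b)`.
#' @param new_symbol the fresh non-terminal id replacing the bigram.
#' @return A list with `merges` (physical reference merges) and `logical`
#'   (logical occurrences in the target they stand for).
#' @export
substitute_in_reference <- function(state, bigram, new_symbol) {
  a <- bigram[1L]; b <- bigram[2L]; z <- as.integer(new_symbol)
  cids <- chain_ids(state)
  cpos <- integer(length(state$ph_type))
  cpos[cids] <- seq_along(cids)
  merges <- 0L
  logical_n <- 0L
  c1 <- state$ref_head
  while (c1 != 0L) {
    c2 <- state$ref_next[c1]
    if (c2 == 0L) break
    if (state$ref_sym[c1] == a && state$ref_sym[c2] == b) {
      part <- stab_partial(state, c1, c2)
      if (length(part$end_side) || length(part$start_side)) {
        stop("internal error: unresolved source boundary at substitution time")
      }
      cov <- stab_covering(state, c1, c2)
      if (length(cov)) {
        cov <- cov[order(cpos[cov])]
        for (p in cov) {
          at_start <- state$ph_s[p] == c1
          at_end <- state$ph_e[p] == c2
          lam <- if (!at_start) {
            state$ref_sym[state$ref_prev[c1]]
          } else {
            q <- state$ph_prev[p]
            if (q == 0L) NA_integer_
            else if (state$ph_type[q] == 1L && state$ph_e[q] == c2) z
            else ph_last_sym(state, q)
          }
          rho <- if (!at_end) {
            state$ref_sym[state$ref_next[c2]]
          } else {
            q <- state$ph_next[p]
            if (q == 0L) NA_integer_ else ph_first_sym(state, q)
          }
          bt_bump(state, lam, a, -1L)
          bt_bump(state, b, rho, -1L)
          bt_bump(state, a, b, -1L)
          bt_bump(state, lam, z, 1L)
          bt_bump(state, z, rho, 1L)
          logical_n <- logical_n + 1L
        }
        state$ref_sym[c1] <- z
        nn <- state$ref_next[c2]
        state$ref_next[c1] <- nn
        if (nn != 0L) state$ref_prev[nn] <- c1
        state$ref_alive[c2] <- FALSE
        remap <- which(state$ph_type == 1L & state$ph_e == c2)
        if (length(remap)) state$ph_e[remap] <- c1
        merges <- merges + 1L
        c1 <- state$ref_next[c1]
      } else {
        c1 <- c2
      }
    } else {
      c1 <- c2
    }
  }
  list(merges = merges, logical = logical_n)
}

#' Substitute a bigram inside explicit phrases
#'
#' Standard RePair replacement over every explicit phrase in chain order,
#' leftmost-first and non-overlapping within runs, with frequency updates
#' for destroyed and created neighbour bigrams (including bigrams crossing
#' into adjacent phrases).
#'
#' @param state an engine state.
#' @param bigram integer `c(a, b)`.
#' @param new_symbol the fresh non-terminal id.
#' @return Number of replacements performed.
#' @export
substitute_in_explicit <- function(state, bigram, new_symbol) {
  a <- bigram[1L]; b <- bigram[2L]; z <- as.integer(new_symbol)
  reps <- 0L
  id <- state$ph_head
  while (id != 0L) {
    if (state$ph_type[id] == 2L) {
      v <- state$ph_syms[[id]]
      n <- length(v)
      if (n >= 2L && any(v[-n] == a & v[-1L] == b)) {
        qp <- state$ph_prev[id]
        qn <- state$ph_next[id]
        prev_t <- if (qp == 0L) NA_integer_ else ph_last_sym(state, qp)
        next_t <- if (qn == 0L) NA_integer_ else ph_first_sym(state, qn)
        out <- integer(n)
        oi <- 0L
        i <- 1L
        while (i <= n) {
          if (i < n && v[i] == a && v[i + 1L] == b) {
            lam <- if (oi > 0L) out[oi] else prev_t
            rho <- if (i + 2L <= n) v[i + 2L] else next_t
            bt_bump(state, lam, a, -1L)
            bt_bump(state, b, rho, -1L)
            bt_bump(state, a, b, -1L)
            bt_bump(state, lam, z, 1L)
            bt_bump(state, z, rho, 1L)
            oi <- oi + 1L
            out[oi] <- z
            i <- i + 2L
            reps <- reps + 1L
          } else {
            oi <- oi + 1L
            out[oi] <- v[i]
            i <- i + 1L
          }
        }
        state$ph_syms[[id]] <- out[seq_len(oi)]
      }
    }
    id <- state$ph_next[id]
  }
  reps
}
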