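# Engine mechanics: interval construction, frequency table, occurrence
# classification, boundary resolution, substitution. The worked micro
# example (T = TGAAACTAAATGCTC against R = GAAACT, alphabet ids A=0 C=1
# G=2 T=3) recurs throughout.

worked_state <- function() {
  p <- rlz_parse("TGAAACTAAATGCTC", "GAAACT")
  st <- intervals_from_pairs(p, "GAAACT")
  init_frequencies(st)
  st
}

test_that("pairs become inclusive intervals and literals become explicit phrases", {
  p <- rlz_parse("TGAAACTAAATGCTC", "GAAACT")
  st <- intervals_from_pairs(p, "GAAACT")
  iv <- phrase_intervals(st)
  expect_identical(iv$s, c(5L, 0L, 1L, 5L, 0L, 4L, 4L))
  expect_identical(iv$e, c(5L, 5L, 3L, 5L, 0L, 5L, 4L))
  expect_true(all(iv$type == "non_explicit"))

  # a single pair spanning the whole reference
  st2 <- intervals_from_pairs(rlz_parse("GAAACT", "GAAACT"), "GAAACT")
  iv2 <- phrase_intervals(st2)
  expect_identical(nrow(iv2), 1L)
  expect_identical(c(iv2$s, iv2$e), c(0L, 5L))

  # a literal pair seeds a one-symbol explicit phrase
  st3 <- intervals_from_pairs(rlz_parse("ACNG", "ACGT"), "ACGT")
  iv3 <- phrase_intervals(st3)
  expect_identical(iv3$type, c("non_explicit", "explicit", "non_explicit"))
  expect_identical(iv3$n_syms[2], 1L)

  bad <- data.frame(pos = 9L, len = 3L, literal = FALSE, byte = NA_integer_)
  expect_error(intervals_from_pairs(bad, "ACGT"), "outside reference")
})

test_that("initial frequencies equal brute-force counts over the target", {
  st <- worked_state()
  bt <- bigram_table(st)
  expect_identical(sum(bt$count), 14L)          # |T| - 1
  aa <- bt$count[bt$a == 0L & bt$b == 0L]
  expect_identical(aa, 4L)
  want <- bigram_counts(materialize(st))
  have <- structure(bt$count, names = paste0(bt$a, "_", bt$b))
  expect_mapequal(as.list(have), as.list(want))

  # self-parse: counts equal brute-force counts over R itself
  stR <- intervals_from_pairs(rlz_parse("GAAACT", "GAAACT"), "GAAACT")
  init_frequencies(stR)
  btR <- bigram_table(stR)
  haveR <- structure(btR$count, names = paste0(btR$a, "_", btR$b))
  expect_mapequal(as.list(haveR), as.list(bigram_counts(materialize(stR))))
})

test_that("peek returns the maximal bigram and NULL at termination", {
  st <- worked_state()
  expect_identical(peek_max_bigram(st), c(0L, 0L))  # AA

  # all counts at most one: done
  st1 <- intervals_from_pairs(rlz_parse("ACGT", "ACGT"), "ACGT")
  init_frequencies(st1)
  expect_null(peek_max_bigram(st1))
})

test_that("tie policies are honoured: lex is smallest pair, lra/insertion return the first-inserted never-reaccessed bigram", {
  # abababa: ab and ba both occur 3 times; ab is seen first
  for (pol in c("lex", "insertion", "lra")) {
    st <- intervals_from_pairs(rlz_parse("abababa", "ab"), "ab",
                               tie_policy = pol)
    init_frequencies(st)
    expect_identical(peek_max_bigram(st), c(0L, 1L), label = pol)
  }
  # lex picks (a,b) among the three bigrams tied at 2 in abbcabbc
  st <- intervals_from_pairs(rlz_parse("abbcabbc", "abc"), "abc")
  init_frequencies(st)
  expect_identical(peek_max_bigram(st), c(0L, 1L))
})

test_that("occurrences are classified into interior, boundary and explicit sets", {
  # worked example: every AA occurrence lies fully within phrases
  st <- worked_state()
  cl <- classify_occurrences(st, c(0L, 0L))
  expect_length(cl$interior, 2)   # reference cells (1,2) and (2,3)
  expect_length(cl$source_boundary, 0)
  expect_length(cl$phrase_boundary, 0)
  expect_length(cl$explicit, 0)
  expect_identical(cl$interior[[1]]$cells, c(1L, 2L))
  expect_identical(cl$interior[[1]]$phrases, c(2L, 3L))  # (0,5) and (1,3)

  # baba against ab: both ba occurrences span phrase boundaries
  st2 <- intervals_from_pairs(rlz_parse("baba", "ab"), "ab")
  init_frequencies(st2)
  cl2 <- classify_occurrences(st2, c(1L, 0L))  # ba
  expect_length(cl2$phrase_boundary, 2)
  expect_length(cl2$interior, 0)
  expect_identical(cl2$phrase_boundary[[1]]$left, 1L)
  expect_identical(cl2$phrase_boundary[[2]]$left, 2L)

  # abbcabbc against abc: the single reference ab is interior for the
  # (0,1) phrases and a source boundary (start side) for the (1,2) phrases
  st3 <- intervals_from_pairs(rlz_parse("abbcabbc", "abc"), "abc")
  init_frequencies(st3)
  cl3 <- classify_occurrences(st3, c(0L, 1L))
  expect_length(cl3$interior, 1)
  expect_identical(cl3$interior[[1]]$cells, c(0L, 1L))
  expect_identical(cl3$interior[[1]]$phrases, c(1L, 3L))
  expect_length(cl3$source_boundary, 2)
  expect_true(all(vapply(cl3$source_boundary, `[[`, "", "side") == "start"))
})

test_that("phrase boundary resolution extracts the two characters without changing the text", {
  st <- intervals_from_pairs(rlz_parse("bab", "ab"), "ab")
  init_frequencies(st)
  before <- materialize(st)
  ok <- resolve_phrase_boundary(st, c(1L, 0L), 1L)  # ba across P1|P2
  expect_true(ok)
  expect_identical(materialize(st), before)
  iv <- phrase_intervals(st)
  # P1 (single b) was emptied and removed; explicit "ba"; P2 shrank to (1,1)
  expect_identical(iv$type, c("explicit", "non_explicit"))
  expect_identical(iv$n_syms[1], 2L)
  expect_identical(c(iv$s[2], iv$e[2]), c(1L, 1L))
})

test_that("against an adjacent explicit phrase only the non-explicit side loses a character", {
  # chain: (1,1)"b" | (0,0)"a" | explicit "N"; bigram aN crosses P2|E
  st <- intervals_from_pairs(rlz_parse("baN", "ab"), "ab")
  init_frequencies(st)
  before <- materialize(st)
  aN <- c(0L, 2L)  # bytes N(78) < a(97) < b(98): N=0... check via alphabet
  al <- st$alpha
  aN <- c(al$byte2id[utf8ToInt("a") + 1L], al$byte2id[utf8ToInt("N") + 1L])
  expect_true(resolve_phrase_boundary(st, aN, 2L))
  expect_identical(materialize(st), before)
  iv <- phrase_intervals(st)
  expect_identical(iv$type, c("non_explicit", "explicit"))
  expect_identical(iv$n_syms, c(1L, 2L))  # "b" | "aN"

  # an occurrence not at the named boundary is rejected as a no-op
  st2 <- intervals_from_pairs(rlz_parse("bab", "ab"), "ab")
  init_frequencies(st2)
  snap <- phrase_intervals(st2)
  expect_false(resolve_phrase_boundary(st2, c(0L, 1L), 1L))  # ab, not ba
  expect_identical(phrase_intervals(st2), snap)
})

test_that("source boundary resolution shrinks partially overlapped intervals", {
  st <- intervals_from_pairs(rlz_parse("abbcabbc", "abc"), "abc")
  init_frequencies(st)
  before <- materialize(st)
  moved <- resolve_source_boundary(st, c(0L, 1L), 0L)
  expect_identical(moved, 2L)  # both (1,2) phrases drop their first char
  expect_identical(materialize(st), before)
  iv <- phrase_intervals(st)
  ne <- iv[iv$type == "non_explicit", ]
  expect_identical(ne$s, c(0L, 2L, 0L, 2L))
  expect_identical(ne$e, c(1L, 2L, 1L, 2L))
  expect_identical(sum(iv$type == "explicit"), 2L)

  # no overlapping phrase: state untouched
  st2 <- worked_state()
  snap <- phrase_intervals(st2)
  expect_identical(resolve_source_boundary(st2, c(0L, 0L), 1L), 0L)
  expect_identical(phrase_intervals(st2), snap)
})

test_that("a phrase overlapped at both ends is emptied into explicit storage", {
  # R=abab, T=ba: the single phrase (1,2) is hit at its start by the ab at
  # cells (0,1) and at its end by the ab at cells (2,3)
  st <- intervals_from_pairs(rlz_parse("ba", "abab"), "abab")
  init_frequencies(st)
  before <- materialize(st)
  resolve_source_boundary(st, c(0L, 1L), 0L)
  resolve_source_boundary(st, c(0L, 1L), 2L)
  expect_identical(materialize(st), before)
  iv <- phrase_intervals(st)
  expect_identical(iv$type, "explicit")  # emptied phrase removed, explicits merged
  expect_identical(iv$n_syms, 2L)
})

test_that("reference substitution merges once per physical occurrence and keeps counts exact", {
  st <- worked_state()
  res <- substitute_in_reference(st, c(0L, 0L), 4L)
  expect_identical(res$merges, 1L)   # the two AA occurrences overlap
  expect_identical(res$logical, 2L)  # the merged one is covered by (0,5) and (1,3)
  m <- materialize(st)
  expect_identical(length(m), 13L)
  # T G 4 A C T 4 A T G C T C with ids A=0 C=1 G=2 T=3
  expect_identical(m, c(3L, 2L, 4L, 0L, 1L, 3L, 4L, 0L, 3L, 2L, 1L, 3L, 1L))
  bt <- bigram_table(st)
  have <- structure(bt$count, names = paste0(bt$a, "_", bt$b))
  expect_mapequal(as.list(have), as.list(bigram_counts(m)))
})

test_that("count updates are weighted by the number of covering phrases", {
  T <- strrep("GAAACT", 3)
  st <- intervals_from_pairs(rlz_parse(T, "GAAACT"), "GAAACT")
  init_frequencies(st)
  res <- substitute_in_reference(st, c(0L, 0L), 4L)
  expect_identical(res$merges, 1L)
  expect_identical(res$logical, 3L)  # one physical merge, three covering phrases
  bt <- bigram_table(st)
  have <- structure(bt$count, names = paste0(bt$a, "_", bt$b))
  expect_mapequal(as.list(have), as.list(bigram_counts(materialize(st))))
})

test_that("explicit substitution is standard RePair with leftmost-first runs", {
  # all-literal parses produce a single explicit phrase
  st <- intervals_from_pairs(rlz_parse("baba", "X"), "X")
  init_frequencies(st)
  al <- st$alpha
  ba <- c(al$byte2id[utf8ToInt("b") + 1L], al$byte2id[utf8ToInt("a") + 1L])
  z <- st$sigma
  expect_identical(substitute_in_explicit(st, ba, z), 2L)
  expect_identical(materialize(st), c(z, z))

  st2 <- intervals_from_pairs(rlz_parse("aaa", "X"), "X")
  init_frequencies(st2)
  al2 <- st2$alpha
  a <- al2$byte2id[utf8ToInt("a") + 1L]
  z2 <- st2$sigma
  expect_identical(substitute_in_explicit(st2, c(a, a), z2), 1L)
  expect_identical(materialize(st2), c(z2, a))  # first occurrence replaced
  bt <- bigram_table(st2)
  have <- structure(bt$count, names = paste0(bt$a, "_", bt$b))
  expect_mapequal(as.list(have), as.list(bigram_counts(materialize(st2))))

  # no explicit occurrences: nothing happens
  st3 <- worked_state()
  expect_identical(substitute_in_explicit(st3, c(0L, 0L), 4L), 0L)
})

test_that("materialization expands the chain in order", {
  st <- worked_state()
  alpha <- st$alpha
  expect_identical(materialize(st),
                   rlzrepair:::encode_ids("TGAAACTAAATGCTC", alpha))
})
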