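# The full compression loop: equivalence with naive RePair, losslessness on
# adversarial inputs, conservation, amortization, termination.

test_that("micro examples produce the exact RePair grammar", {
  res <- rlz_repair("abab", "ab")
  expect_identical(nrow(res$grammar$rules), 1L)
  expect_identical(unname(res$grammar$rules[1, ]), c(2L, 0L, 1L))
  expect_identical(res$grammar$start_sequence, c(2L, 2L))
  expect_same_grammar(res$grammar, naive_repair("abab", alphabet = alphabet_over("abab", "ab")))

  one <- rlz_repair("A", "GAAACT")
  expect_identical(nrow(one$grammar$rules), 0L)
  expect_identical(expand_grammar(one$grammar), "A")
})

test_that("boundary resolution conserves the working sequence; substitutions shrink it by the replacement count", {
  set.seed(21)
  for (i in 1:20) {
    alpha <- c("a", "b", "c")[1:sample(2:3, 1)]
    T <- rand_str(sample(5:60, 1), alpha)
    R <- rand_str(sample(2:12, 1), alpha)
    st <- intervals_from_pairs(rlz_parse(T, R), R)
    init_frequencies(st)
    x <- peek_max_bigram(st)
    if (is.null(x)) next
    before <- materialize(st)
    rlzrepair:::resolve_all_boundaries(st, x[1], x[2])
    expect_identical(materialize(st), before)
    z <- st$next_id
    st$rules <- rbind(st$rules, c(z, x[1], x[2]))
    st$next_id <- z + 1L
    ref <- substitute_in_reference(st, x, z)
    em <- substitute_in_explicit(st, x, z)
    after <- materialize(st)
    expect_identical(length(after), length(before) - ref$logical - em)
  }
})

test_that("the engine reproduces naive RePair grammars on random instances", {
  set.seed(22)
  for (i in 1:40) {
    alpha <- c("a", "b", "c", "d")[1:sample(2:4, 1)]
    T <- rand_str(sample(2:120, 1), alpha)
    R <- rand_str(sample(1:40, 1), alpha)
    res <- rlz_repair(T, R, debug_recount = TRUE)
    want <- naive_repair(T, alphabet = alphabet_over(T, R))
    expect_same_grammar(res$grammar, want)
    expect_identical(expand_grammar(res$grammar), T)
  }
})

test_that("adversarial inputs compress losslessly and match the oracle", {
  cases <- list(
    list(T = strrep("a", 40), R = "a", label = "run against |R| = 1"),
    list(T = strrep("ab", 30), R = "ab", label = "alternating run"),
    list(T = "NNNNXYXYNN", R = "ACGT", label = "target disjoint from reference"),
    list(T = "ACGTACGTAC", R = "ACGTACGTAC", label = "target equals reference"),
    list(T = strrep("GAAACT", 8), R = "GAAACT", label = "concatenated copies"))
  for (cs in cases) {
    res <- rlz_repair(cs$T, cs$R, debug_recount = TRUE)
    expect_identical(expand_grammar(res$grammar), cs$T, label = cs$label)
    want <- naive_repair(cs$T, alphabet = alphabet_over(cs$T, cs$R))
    expect_same_grammar(res$grammar, want)
    expect_identical(validate_grammar(res$grammar), character(0))
  }
})

test_that("physical merges amortize over copies while frequency deltas scale", {
  merges1 <- integer(0)
  freqs1 <- integer(0)
  for (c in c(2L, 4L, 8L)) {
    res <- rlz_repair(strrep("GAAACT", c), "GAAACT")
    merges1 <- c(merges1, res$stats$ref_merges[1])
    freqs1 <- c(freqs1, res$stats$freq[1])
    expect_identical(expand_grammar(res$grammar), strrep("GAAACT", c))
  }
  expect_identical(length(unique(merges1)), 1L)  # independent of c
  expect_identical(freqs1, c(4L, 8L, 16L))       # 2c occurrences of AA
})

test_that("the loop terminates with fresh contiguous ids and no repeated bigram", {
  res <- rlz_repair("TGAAACTAAATGCTC", "GAAACT", debug_recount = TRUE)
  g <- res$grammar
  k <- nrow(g$rules)
  expect_identical(g$rules[, "lhs"], g$sigma + seq_len(k) - 1L)
  final <- materialize(res$state)
  if (length(final) > 1L) {
    expect_true(max(bigram_counts(final)) <= 1L)
  }
  # working length strictly decreases round over round
  expect_true(all(res$stats$logical_replacements >= 1L))
})

test_that("alternative tie policies still yield valid lossless grammars", {
  set.seed(23)
  for (pol in c("insertion", "lra")) {
    for (i in 1:5) {
      T <- rand_str(sample(10:80, 1), c("a", "b"))
      R <- rand_str(sample(2:10, 1), c("a", "b"))
      res <- rlz_repair(T, R, tie_policy = pol, debug_recount = TRUE)
      expect_identical(expand_grammar(res$grammar), T)
      expect_identical(validate_grammar(res$grammar), character(0))
    }
  }
})
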