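---
title: "Grammar compression over RLZ parses: the method behind rlzrepair"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grammar compression over RLZ parses: the method behind rlzrepair}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rlzrepair)
```

## The problem

RePair is a grammar compressor with strong combinatorial properties: it
repeatedly replaces the most frequent adjacent symbol pair (bigram) of a
sequence with a fresh non-terminal until no pair repeats, yielding a
straight-line program whose rules expose hierarchical structure in the data.
Its weakness is memory: the whole text is held and rewritten in place, which
is prohibitive for pangenome-scale collections that are nevertheless highly
repetitive.

Relative Lempel-Ziv (RLZ) parsing is the complementary tool: given a
reference string $R$, a target $T$ is factorized greedily into phrases, each
the longest prefix of the remaining suffix of $T$ occurring in $R$, encoded
as a pair $(p, \ell)$ — source position and length. On a collection of
near-identical sequences parsed against a representative reference, the
parse is tiny. But RLZ by itself exposes no hierarchical structure.

`rlzrepair` implements the combination: run the RePair loop *on the RLZ
parse*. Phrases are kept as intervals $(s, e) = (p, p+\ell-1)$ over a
mutable reference, so replacing a bigram once in the reference substitutes
it simultaneously in every phrase that spans the occurrence. If $n$ phrases
cover a reference occurrence, one physical merge performs $n$ logical
replacements. The result is — occurrence for occurrence, rule for rule —
the RePair grammar of $T$, built with far fewer physical operations.

## Data model

* **Linked reference.** $R$ is stored as a doubly linked list embedded in an
  array. A merge writes the new symbol into the left cell and unlinks the
  right cell; absolute indices of surviving cells never change, so phrase
  intervals stay valid. Positions are therefore *logical*: "next" means the
  next live cell, not index $+1$.
* **Non-explicit phrases** are intervals $(s, e)$ into the reference.
  Substitutions in $R$ propagate to them for free.
* **Explicit phrases** are literal symbol runs holding characters that had
  to be cut loose from intervals (and RLZ literals, under the default
  `policy = "literal"`). They are processed exactly like ordinary RePair
  text.
* **Phrase chain.** The working representation of $T$ is the ordered chain
  of phrases; `materialize()` expands it to the current symbol sequence.
  Adjacent explicit phrases are always merged and emptied phrases removed.
* **Bigram table.** Counts over the materialized sequence, computed once
  from the phrase structure at start-up and maintained incrementally: every
  replacement applies the local update algebra (decrement the two destroyed
  neighbour pairs and the replaced pair itself, increment the two created
  pairs), weighted by the number of covering phrases and consulting the
  adjacent phrase's boundary character when an occurrence touches a phrase
  edge.

## One round of the loop

1. **Select** the most frequent bigram $X = ab$; stop when no bigram occurs
   more than once.
2. **Resolve boundaries.** Two situations would let a replacement corrupt a
   phrase: $X$ spans two consecutive phrases of the chain (*phrase boundary
   condition*), or a reference occurrence of $X$ overlaps exactly one
   endpoint cell of an interval (*source boundary condition*). In both
   cases the affected boundary characters are copied out into adjacent
   explicit phrases and the intervals shrink
   ($(s, e-1)$, $(s+1, e)$, or $(s+1, e-1)$ when both ends participate).
   Resolutions cascade — a shrunken interval can expose a new overlap, an
   extracted character a new boundary bigram — so the engine iterates to a
   fixed point. Every step moves at least one character into explicit
   storage, so the fixed point is reached; crucially, resolution never
   changes the materialized sequence, only its bookkeeping (a conservation
   property the tests assert directly).
3. **Substitute.** Reference occurrences of $X$ are scanned left to right
   and merged when fully covered by at least one phrase (leftmost-first
   within runs of identical symbols, so `aaaa` becomes `ZZ` and `aaa`
   becomes `Za`); occurrences covered by no phrase contribute nothing to
   $T$ and are skipped, which keeps the table synchronized with $T$ rather
   than with $R$. Explicit phrases are then rewritten like standard RePair.
   A rule $Z \to ab$ is recorded, with $Z = \sigma + (\text{round index})$.

The final grammar is the terminal alphabet (bytes of $T \cup R$, numbered
ascending), the recorded rules, and the materialized chain as the start
sequence $C$.

## Correctness and the dual-route tests

The package carries an intentionally naive array-based RePair
(`naive_repair()`: full recount each round, same tie and run policies) and a
brute-force RLZ factorizer in the test helpers. The central property —
asserted on the worked micro example and hundreds of seeded random
instances — is that `rlz_repair()` and `naive_repair()` produce *identical*
rule sets and start sequences, and that expansion returns the input
bit-exactly. In debug mode (`debug_recount = TRUE`) the engine additionally
recounts every bigram by brute force after each round and aborts on any
divergence.

## Tie-breaking

When several bigrams share the maximal frequency, the published
descriptions leave the choice open (the original RePair authors call it of
minor importance and use the least recently accessed candidate, which is
nondeterministic under hash-table iteration). `rlzrepair` must be able to
assert grammar equality between two independent implementations, so the
default tie policy is fully state-determined: the lexicographically
smallest $(a, b)$ id pair. A least-recently-accessed order cannot be shared
exactly with a recount-based oracle — the engine and the oracle encounter
newly created bigrams in different orders within a round — so `"lra"`
(accesses are count updates and selections, insertion as the initial
access) and `"insertion"` (first-seen order) are provided as options and
tested for validity and losslessness, but grammar equality is asserted
under `"lex"` only. Run handling is leftmost-first everywhere; the oracle's
`run_policy = "last"` emulates the rightmost-first convention of Navarro's
implementation, which performs the same number of replacements but names
different symbols.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `policy` | `"literal"` | Target characters absent from $R$ become one-symbol explicit phrases; `"strict"` errors instead. |
| `tie_policy` | `"lex"` | Frequency tie-break (above). |
| `debug_recount` | `FALSE` | Brute-force count verification per round (quadratic; testing only). |
| `separator` (FASTA reader) | none | Optional single byte between records; by default compression runs on the raw concatenation. |

The synthetic generator (`generate_collection()`) emulates the structure of
repetitive biological collections: a random base sequence (default DNA
alphabet) with `num_copies` descendants carrying per-position substitutions
(`substitution_rate`, default 0.01 — the divergence scale of closely
related genomes) and geometric-length indels (`indel_rate`, default 0.001).
It reproduces the *repetitiveness* that makes reference-based parsing
effective; it does not model rearrangements, duplications, uneven coverage,
or real base composition, so passing tests demonstrate algorithmic
correctness and the amortization behaviour, not field performance on any
particular dataset.

## Numerical and degenerate-input choices

* Coordinates are 0-based with inclusive interval ends throughout the
  public interface.
* On equal-length longest matches the parser takes the smallest source
  position; matching is a suffix array queried under C collation (byte
  order), so results are locale-independent.
* Phrase-length statistics report the population standard deviation.
* Degenerate inputs — a one-character target, $|R| = 1$, targets disjoint
  from the reference alphabet, $T = R$, long single-symbol runs — all
  reduce to ordinary RePair behaviour via the explicit-phrase path and are
  covered by tests.
* An interval shrunk past zero length is removed from the chain; a
  reference occurrence covered by zero phrases is never merged.

## Problem sizes used by the test suite

The randomized equivalence suite runs 200 seeded instances with targets up
to 300 characters and references up to 60, plus adversarial fixtures; the
end-to-end demonstration compresses 50 mutated copies of a 2 kb base
(≈100 kb of target) against the base sequence and verifies losslessness and
the file-format round trip. These sizes were chosen to exercise every code
path — boundary cascades included — while keeping the pure-R engine's
runtime pleasant; the algorithm itself has no size-specific logic.

## Known limitations

* The engine favours clarity over constant-factor speed: the auxiliary
  structures of a production C++ implementation (max-heap, augmented
  interval tree, boundary hash maps) are realized as vectorised scans with
  the same contracts. Inputs in the tens of megabytes are out of scope.
* The suffix-array construction materializes suffix strings and is intended
  for references up to a few hundred kilobytes.
* Texts are handled as R strings; embedded NUL bytes are not supported.
* The grammar file format is the package's own plain-text RLZRP1; it is not
  binary-compatible with existing RePair tools, and no random-access or
  substring-extraction machinery over the SLP is provided.
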