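# rlzrepair

RePair grammar compression over Relative Lempel-Ziv parses, in R.

Grammar compressors of the RePair family repeatedly replace the most
frequent adjacent symbol pair (bigram) of a text with a fresh non-terminal,
producing a straight-line program — a start sequence `C` plus binary rules
`R` — that both compresses the text and exposes its hierarchical structure.
RePair's problem is memory: it rewrites the whole text in place. For
repetitive collections (pangenomes, assemblies of near-identical genomes)
the Relative Lempel-Ziv (RLZ) parse against a reference `R` is tiny: each
phrase is the longest prefix of the remaining target that occurs in the
reference, encoded as a pair `(p, ℓ)`.

`rlzrepair` runs the RePair loop *on the parse*: phrases are intervals
`(s, e) = (p, p + ℓ − 1)` over a linked-list reference, so one physical
bigram merge in the reference substitutes every logical occurrence that the
covering phrases stand for. Characters that a merge would invalidate — a
bigram spanning two phrases, or a reference occurrence overlapping exactly
one endpoint of an interval — are made explicit first. The output is, rule
for rule, the RePair grammar of the target, constructed with far fewer
physical replacements. The package includes a deliberately naive RePair
used as a ground-truth oracle, a documented plain-text grammar format
(`RLZRP1`) with full decompression, FASTA input, a synthetic-collection
generator, and a command-line front end (`exec/rlzrepair`).

Intended users: people studying grammar-based compression and repetitive
sequence collections, and anyone needing a transparent, fully tested
reference implementation of interval-based RePair to check an optimized
implementation against.

## Worked example

The micro example: target `T = TGAAACTAAATGCTC` against reference
`R = GAAACT`.

```r
library(rlzrepair)

p <- rlz_parse("TGAAACTAAATGCTC", "GAAACT")
p
#>   pos len literal byte
#> 1   5   1   FALSE   NA
#> 2   0   6   FALSE   NA
#> 3   1   3   FALSE   NA
#> 4   5   1   FALSE   NA
#> 5   0   1   FALSE   NA
#> 6   4   2   FALSE   NA
#> 7   4   1   FALSE   NA
```

Seven phrases: `(5,1)` is the single `T` at reference position 5, `(0,6)`
is all of `GAAACT`, and so on; `expand_parse(p, "GAAACT")` returns the
target exactly. Compression:

```r
res <- rlz_repair("TGAAACTAAATGCTC", "GAAACT")
res
#> RLZ-RePair result: 4 rounds, 4 rules, |C| = 7
#>   physical merges: 5 (reference 3, explicit 2); logical replacements: 8; saved: 3

res$stats[1, c("a", "b", "freq", "ref_merges")]
#>   a b freq ref_merges
#> 1 0 0    4          1
```

Round one picks `AA` (ids `0 0`, frequency 4). Its two reference
occurrences overlap, so a single physical merge — covered by the phrases
`(0,5)` and `(1,3)` — performs both logical replacements, shrinking the
working sequence from 15 to 13 symbols. Overall, 8 logical replacements
cost only 5 physical merges. The grammar is exactly what naive RePair
produces and decompresses losslessly:

```r
identical(expand_grammar(res$grammar), "TGAAACTAAATGCTC")
#> [1] TRUE
g2 <- naive_repair("TGAAACTAAATGCTC",
                   alphabet = alphabet_over("TGAAACTAAATGCTC", "GAAACT"))
identical(res$grammar$rules, g2$rules)
#> [1] TRUE
```

On repetitive input the amortization is what matters: for `c` concatenated
copies of the reference, the frequency of the top bigram grows with `c`
while round-one physical merges stay constant.

The same pipeline from a shell:

```sh
rlzrepair compress --input target.fa --reference ref.fa --output out.rlzrp --fasta
rlzrepair decompress --grammar out.rlzrp --output roundtrip.txt
```

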