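Package: rlzrepair
Title: RePair Grammar Compression over Relative Lempel-Ziv Parses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds RePair grammars for repetitive texts by first computing a
    Relative Lempel-Ziv (RLZ) factorization of the target against a reference
    and then running the RePair bigram-replacement loop over phrase intervals
    on the reference, so that one physical merge in the reference substitutes
    many logical occurrences at once. Includes an exact naive RePair
    implementation used as a ground-truth oracle, a plain-text grammar format
    with serialization and full decompression, FASTA input handling, and a
    deterministic generator of synthetic repetitive sequence collections.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: Biostrings, withr
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
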