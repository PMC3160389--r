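Package: ssralign
Title: Slippage-Aware Realignment of Microsatellite Loci in Multiple
    Sequence Alignments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Post-processes multiple sequence alignments that span simple
    sequence repeat (SSR, microsatellite) loci. Generic aligners place
    copies of different repeat units in the same columns of a compound or
    imperfect SSR, creating spurious substitutions; because SSR variation
    arises from replication slippage, it should align as insertions and
    deletions instead. ssralign repartitions a user-delimited SSR window
    into non-overlapping per-repeat-unit blocks, pads each block with gaps
    to the longest run, and places interrupting residues after the
    slippage gap. Companion tools compute p-distances, mean pairwise
    distance and UPGMA trees so alignments can be compared before and
    after realignment, and a synthetic allele generator produces panels
    with known repeat structure for testing. A command-line interface
    covers realignment, comparison, simulation, and distance/tree export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
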