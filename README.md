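# ssralign

Slippage-aware realignment of microsatellite (SSR) loci in multiple
sequence alignments, for anyone using SSR markers in diversity or
phylogenetic work who needs the repeat region of an alignment to reflect
how repeats actually mutate.

## The problem

Microsatellite alleles at one locus differ mainly by replication slippage:
whole repeat units are gained or lost, so allelic variation is
insertion/deletion-like, while the flanks stay conserved. General aligners
are built for substitution-dominated sequence, and on a *compound* SSR —
adjacent runs of different units such as (TA)<sub>a</sub>(CA)<sub>b</sub> —
they stack copies of one unit in the same columns as copies of another
whenever copy numbers differ. Every such overlap column is scored as a
substitution downstream, inflating pairwise distances and distorting trees
with differences the mutation process never produced.

## What the package does

Given an alignment, the ordered repeat units, and the 1-based column window
`[first, last]` of the locus, `realign()` rewrites only that window:

1. per sequence, the window is degapped and decomposed in one greedy
   left-to-right pass into a prefix, then for each unit its maximal tandem
   run and any unmatched (interrupting) residues before the next unit;
2. each unit *i* gets its own column field of width
   C<sub>i</sub>·|unit<sub>i</sub>| (C<sub>i</sub> = highest copy number in
   the panel); runs are left-aligned, so copy-number differences become
   terminal gaps — the slippage site; unmatched residues are right-aligned
   after that gap, directly before the next unit or the 3' flank.

No column ever mixes two units, and `degap(row)` is unchanged for every
sequence — only gap placement moves. On panels whose alleles differ only by
copy number, realignment removes *all* substitution columns, so the mean
pairwise p-distance drops, to exactly 0 in the slippage-only case.

Supporting machinery: FASTA and header+rows table I/O
(`read_alignment()`/`write_alignment()`), p-distance with pairwise deletion
(`p_distance()`, `distance_matrix()`, `mean_pairwise_distance()`), UPGMA
trees (`upgma()`, `write_newick()`), a synthetic allele generator with
ground truth (`sim_config()`, `generate_alleles()`, `case_design()`,
`naive_overlap_alignment()`), and a CLI (`ssr_cli()`, installed script
`inst/scripts/ssralign`) with `realign`, `compare`, `simulate`, `distance`
and `tree` subcommands.

## Worked example

```r
library(ssralign)

aln <- alignment(c(s1 = "GGTATACACAGG", s2 = "GGTATATACAGG"))
realign(aln, ssr_spec("TA CA", first = 3, last = 10))
#> ssr_alignment: 2 sequences x 14 columns
#>   s1 GGTATA--CACAGG
#>   s2 GGTATATACA--GG
```

Both windows hold (TA)(CA) runs — s1 as TA×2 CA×2, s2 as TA×3 CA×1. The TA
field is sized for 3 copies and the CA field for 2, so s1 gains a gap pair
at its TA slippage site and s2 at its CA site. Column-wise, every
difference is now residue-versus-gap; a naive alignment of these two rows
pairs TA against CA in columns 7–8 and scores two substitutions.

The same mechanism at panel scale, with a simulated 26-allele compound
locus (design "B": (TA)<sub>10</sub>(CA)<sub>16</sub> reference motif,
copy-number variation only):

```r
panel <- generate_alleles(case_design("B", seed = 11))
naive <- naive_overlap_alignment(panel)     # left-justified, overlapping
w <- attr(naive, "ssr_window")
compare_realignment(naive, ssr_spec(panel$cfg$units, w[1], w[2]))$report
#> # A tibble: 1 × 5
#>   pd_before pd_after pd_delta length_before length_after
#>       <dbl>    <dbl>    <dbl>         <int>        <int>
#> 1   0.00993        0  0.00993           365          369
```

The naive baseline shows a mean pairwise distance of 0.00993 created
entirely by unit overlaps; after realignment it is exactly 0 and the
alignment is 4 columns longer — the separated unit fields. The summary
`ssr_fraction(100, 397)` → `25.2` gives the percentage of such a locus
occupied by the repeat.

From the shell:

```sh
ssralign realign --in locus.fasta --out locus_ssr.fasta \
  --units "TA CA" --first 151 --last 218
ssralign compare --in locus.fasta --out-prefix locus \
  --units "TA CA" --first 151 --last 218 --report locus.tsv
```

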