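---
title: "Slippage-aware realignment of microsatellite loci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slippage-aware realignment of microsatellite loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssralign)
```

## The problem

Microsatellites (simple sequence repeats, SSRs) are tandem repeats with a
unit period of 1–6 bp. Their characteristic mutation process is replication
slippage: the polymerase gains or loses whole repeat copies, so alleles at
one locus differ mainly in *copy number*, an insertion/deletion-type
difference, while the flanking sequence stays highly conserved.

General-purpose aligners are tuned for substitution-dominated sequence and
treat an SSR window like any other stretch of DNA. In a *compound* SSR —
several adjacent runs of different units, e.g. (TA)~a~(CA)~b~ — this
misleads them: when copy numbers differ between alleles, copies of one unit
end up stacked in the same columns as copies of a *different* unit. Each of
those overlap columns counts as a substitution in downstream distance and
tree estimation, inflating pairwise distances with differences that the
slippage process never produced.

`ssralign` post-processes an existing alignment. Given the ordered repeat
units and the column window of the SSR locus, it rewrites only that window
so that every repeat unit occupies its own block of columns and copy-number
differences appear as gaps, never as substitutions.

## The procedure

For each sequence the window content is taken, gaps discarded, and the
residues decomposed in one greedy left-to-right pass:

1. **Prefix** — residues before the first full copy of unit 1. (If unit 1
   never occurs, the whole window is prefix; the package warns, keeps the
   content, and aligns it right-justified.)
2. **Runs** — at the cursor, the maximal tandem run of the current unit is
   consumed (`match_run()`): *k* copies such that copy *k*+1 does not
   follow.
3. **Unmatched residues** — residues after a run that neither continue it
   nor start the next unit are collected verbatim, one at a time, until the
   next unit's first full copy begins (or, for the last unit, the window
   ends). These are the interrupting residues of an imperfect repeat.

Reassembly (`assemble_blocks()`) then lays the partitions out in parallel
fields. With *P* the longest prefix, *C~i~* the highest copy number of unit
*i* and *U~i~* the longest unmatched stretch after it, every row becomes

```
[prefix, right-aligned | unit_i runs, left-aligned | unmatched_i, right-aligned] ...
          width P              width C_i * |unit_i|        width U_i
```

so all rows share the width *P* + Σ~i~ (*C~i~*·|unit~i~| + *U~i~*). Runs are
left-aligned and padded on the right: the terminal gap *is* the slippage
site. Unmatched residues are right-aligned so that they sit after that gap
and directly before whatever follows — the next repeat unit or the 3'
flank. Columns outside the window are copied untouched.

```{r}
aln <- alignment(c(s1 = "GGTATACACAGG", s2 = "GGTATATACAGG"))
realign(aln, ssr_spec("TA CA", first = 3, last = 10))
```

The decomposition never invents or discards a residue, so
`degap(row)` is identical before and after — realignment changes gap
placement only.

### Parameters and conventions

* **`units`** — the ordered repeat units, supplied by the user exactly as a
  locus is described (e.g. `"TA CA"` for (TA)~a~(CA)~b~). Units are 1–6 bp
  over `ACGT`; adjacent duplicates are rejected because they denote a
  single run. De novo motif discovery is out of scope by design: the locus
  structure is an input, as it is when a marker is published.
* **`first`, `last`** — 1-based inclusive *column* coordinates of the SSR
  window in the input alignment, matching how a locus position is read off
  an alignment viewer. Converted internally to offsets.
* **Gap character** — `-` in output; `.` is accepted on input and
  normalised. Sequences are uppercased; `U` is rejected (DNA only).
* **`N`** matches no unit. This is the conservative reading: an ambiguous
  base cannot positively support a repeat copy, so it flows into the
  prefix/unmatched residues and stays visible as an interruption.

### Decisions where the design was genuinely open

* **Interrupted runs do not resume.** After `TATA g TATA` (units `TA …`),
  the second `TATA` is kept with the interrupting `g` as unmatched residue
  rather than opening a second `TA` field. A single pass with one field per
  listed unit keeps the output width and the block semantics predictable;
  users who consider the downstream copies a separate run can list the unit
  twice in the locus description with an intervening unit, or widen the
  window. This is the main simplification to be aware of for strongly
  imperfect loci.
* **Greedy unit order breaks phase ties.** With overlapping-phase units
  (`TA` then `AT` on `TATAT…`), the earlier unit consumes greedily first;
  the result is deterministic by construction.
* **Windows are degapped per sequence before partitioning.** The input
  window comes from a generic aligner and may contain gaps; keeping them
  would corrupt run matching.
* **Realignment is idempotent**: running `realign()` on its own output
  (with the window updated to the attribute `ssr_window`) reproduces it
  exactly — the partition of an already-partitioned window finds the same
  blocks. This is enforced by a property test.

## Distances and trees

To quantify what realignment changes, the package carries the standard
comparison machinery:

* `p_distance()` — uncorrected proportion of mismatching sites among sites
  where neither sequence is gapped (pairwise deletion). The overall
  pairwise distance of an alignment (`mean_pairwise_distance()`) is the
  mean over all pairs. p-distance with pairwise deletion is the plainest
  choice and is stated here explicitly so results are reproducible;
  distance corrections (JC69 and the like) are deliberately out of scope.
  A fully gapped pair has no comparable sites and yields 0 with a warning.
  `N` is compared like any residue.
* `upgma()` — unweighted pair-group agglomeration: join the closest pair,
  place the node at half the joining distance, average distances weighted
  by cluster size. Ties are broken deterministically in favour of the
  earliest-created cluster pair, since the reference implementations leave
  their internal order unspecified. The result is a rooted ultrametric
  `ape::phylo`; `write_newick()` serialises it with single-quoting for
  labels that contain Newick metacharacters.

The mechanism the package exists for shows up directly in these numbers:
overlap columns pair different units across alleles and register as
substitutions, so the mean pairwise distance of a naively aligned compound
SSR panel is positive even when the alleles differ *only* by slippage.
After realignment every column holds one unit in one phase — each column is
either homogeneous or residue-vs-gap — so those panels collapse to distance
exactly 0 ("slippage collapse"), and in general the mean pairwise distance
can only drop on slippage-only panels.

## The synthetic allele generator

No public allele panels ship with the package; `generate_alleles()`
produces panels with *known* structure instead, so every claim above is
testable against ground truth. An allele is built as
`flank5 + unit1^c1 + … + unitk^ck + flank3` with

* per-unit copy numbers drawn uniformly from configured ranges — the
  slippage-style variation;
* optionally one interrupting base at a random within-run boundary
  (an imperfect SSR; the base is drawn so it cannot extend the run);
* optionally per-site flank substitutions (SNPs).

The truth record (copy numbers, imperfection, SNPs) reconstructs each
emitted sequence exactly, and `naive_overlap_alignment()` produces the
flawed baseline deliberately: SSR cores are left-justified and right-padded,
which is precisely the layout that stacks different units in shared columns.

`case_design()` bundles five ready configurations spanning the common locus
types — a simple perfect dinucleotide locus (A), compound perfect loci of
two to four units (B–D), and a compound imperfect locus with tri- and
hexanucleotide units (E), with reference motifs (TA)~10~, (CA)~16~,
(CG)~14~, (TG)~18~ and (GAA)~4~(GAT)~6~(GAGGAT)~3~. Panels have 26 alleles
by default; copy numbers vary by ±5 around the reference motif (±2 for E),
a spread wide enough that a 26-allele panel essentially always contains
overlap columns while copy numbers stay positive. Flanks are fixed
arbitrary conserved sequences sized so the SSR occupies a realistic
fraction of the locus (~300 bp of flank for A–D, ~700 bp for E). Defaults
are slippage-only (`flank_snp_rate = 0`); design E carries interruptions at
`imperfect_rate = 0.2`.

What the generator does **not** emulate: generational dynamics (no
coalescent or stepwise mutation model, no length-dependent slippage rate),
PCR stutter, sequencing error, and alignment noise in the flanks (flanks
are aligned trivially because they are length-invariant by construction).
Passing tests on these panels therefore demonstrate the combinatorial
correctness of the partition/assembly machinery and the overlap-removal
mechanism — not robustness to every artefact of real trace data.

```{r}
panel <- generate_alleles(case_design("B", seed = 11))
naive <- naive_overlap_alignment(panel)
w <- attr(naive, "ssr_window")
cmp <- compare_realignment(naive, ssr_spec(panel$cfg$units, w[1], w[2]))
cmp$report
```

## Numerical and testing notes

* Coordinates are validated fail-fast with classed conditions
  (`ssralign_bounds_error` etc.); the CLI maps usage/validation errors to
  exit 2 and runtime errors to exit 1.
* Ultrametricity of UPGMA trees is exact up to floating-point addition;
  tests assert root-to-leaf spread below 1e-9.
* The partition scan is cross-checked against an independent oracle — a
  tempered-greedy regular-expression decomposition with the same
  prefix/greedy-run/unmatched semantics — exhaustively on every window up
  to 9 bp over `{T,A,C}` for units `TA, CA` (29,524 windows) and on
  fixed-seed random samples of longer windows (10–12 bp) and of longer
  alphabets/unit sets, including the trinucleotide/hexanucleotide units of
  design E. The exhaustive bound and sample sizes are the suite's chosen
  problem sizes; the property holds identically at smaller and larger
  sweeps we have run.
* Degenerate inputs behave conservatively: an empty window partitions to
  zero-copy blocks; a window with no match of the first unit is kept
  verbatim (with a warning); `copies = 0` blocks occupy zero width unless
  another sequence has copies.

## Limitations

* One SSR window per call; disjoint loci are realigned in separate runs.
* The greedy non-resuming rule understates copy numbers of strongly
  imperfect runs (see above); interrupting residues are preserved but not
  themselves aligned against each other beyond right-justification.
* p-distance/UPGMA are intentionally minimal comparison machinery; for
  publication-grade phylogenetics export the realigned FASTA and use a
  dedicated package.
* Protein sequences and RNA are out of scope.
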