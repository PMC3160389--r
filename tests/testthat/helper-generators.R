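# Shared fixture generators and independent oracles. Everything is built in
# code at test time; randomness is always under a seed set by the caller.

BASES4 <- c("A", "C", "G", "T")

random_alignment <- function(n_seq = 5L, n_col = 40L, gap_rate = 0.15) {
  rows <- vapply(seq_len(n_seq), function(i) {
    ch <- sample(BASES4, n_col, replace = TRUE)
    ch[stats::runif(n_col) < gap_rate] <- "-"
    paste(ch, collapse = "")
  }, "")
  alignment(rows, sprintf("s%02d", seq_len(n_seq)))
}

# every window of the given lengths over an alphabet
all_windows <- function(lengths, alphabet = c("T", "A", "C")) {
  unlist(lapply(lengths, function(L) {
    if (L == 0L) return("")
    do.call(paste0, do.call(expand.grid,
                            c(rep(list(alphabet), L),
                              stringsAsFactors = FALSE)))
  }))
}

random_windows <- function(n, lengths, alphabet = c("T", "A", "C")) {
  vapply(seq_len(n), function(i) {
    L <- sample(lengths, 1L)
    paste(sample(alphabet, L, replace = TRUE), collapse = "")
  }, "")
}

# Independent partition oracle: one tempered-greedy PCRE pattern per unit
# list. `(?:(?!U).)*` consumes residues exactly up to the first position
# where a full copy of U begins, `(?:U)*` then takes the maximal tandem
# run — the same prefix / greedy-run / unmatched semantics, realised by
# the regex engine instead of a positional scan. Vectorised over windows;
# returns a data.frame with prefix, copies.<i>, unmatched.<i> columns.
oracle_partition <- function(windows, units) {
  pat <- paste0("^((?:(?!", units[1L], ").)*)")
  for (i in seq_along(units)) {
    pat <- paste0(pat, "((?:", units[i], ")*)")
    if (i < length(units)) {
      pat <- paste0(pat, "((?:(?!", units[i + 1L], ").)*)")
    }
  }
  pat <- paste0(pat, "(.*)$")
  m <- regexpr(pat, windows, perl = TRUE)
  stopifnot(all(m == 1L))
  cs <- attr(m, "capture.start")
  cl <- attr(m, "capture.length")
  grab <- function(g) substr(windows, cs[, g], cs[, g] + cl[, g] - 1L)
  out <- data.frame(prefix = grab(1L), stringsAsFactors = FALSE)
  for (i in seq_along(units)) {
    run_g <- 2L * i                  # group of the i-th tandem run
    um_g <- 2L * i + 1L              # group of the residues that follow it
    out[[paste0("copies", i)]] <- cl[, run_g] %/% nchar(units[i])
    out[[paste0("unmatched", i)]] <- grab(um_g)
  }
  out
}

# flatten a partition result to the oracle's row layout
partition_row <- function(p) {
  out <- list(prefix = p$prefix)
  for (i in seq_len(nrow(p$blocks))) {
    out[[paste0("copies", i)]] <- p$blocks$copies[i]
    out[[paste0("unmatched", i)]] <- p$blocks$unmatched[i]
  }
  out
}

expect_partition_matches_oracle <- function(windows, units) {
  oracle <- oracle_partition(windows, units)
  got <- lapply(windows, function(w)
    partition_row(suppressWarnings(partition_sequence(w, units))))
  got <- do.call(rbind.data.frame, c(got, stringsAsFactors = FALSE))
  rownames(got) <- rownames(oracle) <- NULL
  expect_identical(got, oracle)
}

# field layout of an assembled window, for overlap/shape checks
field_layout <- function(parts, units) {
  P <- max(vapply(parts, function(p) nchar(p$prefix), 0L))
  C <- apply(vapply(parts, function(p) p$blocks$copies,
                    integer(length(units))), 1L, max)
  U <- apply(vapply(parts, function(p) nchar(p$blocks$unmatched),
                    integer(length(units))), 1L, max)
  list(P = P, C = C, U = U, width = P + sum(C * nchar(units) + U))
}

# every repeat field must hold whole copies of its own unit, then gaps
expect_no_unit_overlap <- function(rows, parts, units) {
  lay <- field_layout(parts, units)
  off <- lay$P
  for (b in seq_along(units)) {
    w <- nchar(units[b])
    fw <- lay$C[b] * w
    field <- substr(rows, off + 1L, off + fw)
    pat <- paste0("^(?:", units[b], ")*-*$")
    expect_true(all(grepl(pat, field)),
                label = sprintf("unit %s field pure in all rows", units[b]))
    off <- off + fw + lay$U[b]
  }
}

# TRUE if every column is either all-equal residues or residue-vs-gap only
zero_substitution_columns <- function(aln) {
  chars <- matrix(unlist(strsplit(aln$rows, "", fixed = TRUE)),
                  nrow = length(aln$rows), byrow = TRUE)
  all(apply(chars, 2L, function(col) {
    r <- unique(col[col != "-"])
    length(r) <= 1L
  }))
}

slippage_panel <- function(case, seed) {
  generate_alleles(case_design(case, seed = seed))
}

realign_panel <- function(panel) {
  naive <- naive_overlap_alignment(panel)
  w <- attr(naive, "ssr_window")
  list(naive = naive,
       realigned = suppressWarnings(
         realign(naive, ssr_spec(panel$cfg$units, w[["first"]], w[["last"]]))))
}
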