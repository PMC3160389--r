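# expected value for the first match_run example, frozen from an
# exhaustive check: 3 is the largest k with strrep("TA", k) a prefix of
# "TATATACA" at position 1 (k = 4 fails).
test_that("match_run counts the maximal greedy tandem run", {
  expect_identical(
    max(which(vapply(0:4, function(k)
      startsWith("TATATACA", strrep("TA", k)), NA))) - 1L,
    3L)
  expect_identical(match_run("TATATACA", 1, "TA"), 3L)
  expect_identical(match_run("TATATACA", 7, "CA"), 1L)
  expect_identical(match_run("GGGG", 1, "TA"), 0L)
  expect_identical(match_run("ACGT", 5, "A"), 0L)  # pos = len + 1 is legal
  expect_error(match_run("ACGT", 6, "A"), class = "ssralign_bounds_error")
})

test_that("degap strips gaps and nothing else", {
  expect_identical(degap("TA--TA"), "TATA")
  expect_identical(degap("----"), "")
  expect_identical(degap("ACGT"), "ACGT")
})

test_that("ssr_spec validates units and window coordinates", {
  sp <- ssr_spec("TA CA", 3, 10)
  expect_identical(sp$units, c("TA", "CA"))
  expect_identical(ssr_spec(c("ta", "ca"), 1, 2)$units, c("TA", "CA"))
  expect_error(ssr_spec("TAACAGG", 1, 10), "6 bp",
               class = "ssralign_argument_error")
  expect_error(ssr_spec("TA TA", 1, 10), class = "ssralign_argument_error")
  expect_error(ssr_spec("TN", 1, 10), class = "ssralign_argument_error")
  expect_error(ssr_spec("TA", 5, 4), class = "ssralign_bounds_error")
  expect_error(ssr_spec("TA", 0, 4), class = "ssralign_bounds_error")
})

test_that("partition_sequence follows the greedy left-to-right trace", {
  p <- partition_sequence("TATACACACA", c("TA", "CA"))
  expect_identical(p$prefix, "")
  expect_identical(p$blocks$copies, c(2L, 3L))
  expect_identical(p$blocks$unmatched, c("", ""))

  p <- partition_sequence("TATAGCACA", c("TA", "CA"))
  expect_identical(p$blocks$copies, c(2L, 2L))
  expect_identical(p$blocks$unmatched, c("G", ""))

  expect_no_warning(p <- partition_sequence("GGTATA", "TA"))
  expect_identical(p$prefix, "GG")
  expect_identical(p$blocks$copies, 2L)

  p <- partition_sequence("", c("TA", "CA"))
  expect_identical(p$prefix, "")
  expect_identical(p$blocks$copies, c(0L, 0L))

  # 'N' matches no unit: it interrupts a run like any foreign residue
  p <- partition_sequence("TANATACA", c("TA", "CA"))
  expect_identical(p$blocks$copies, c(1L, 1L))
  expect_identical(p$blocks$unmatched, c("NATA", ""))

  # a window the first unit never matches stays as prefix, with a warning
  expect_warning(p <- partition_sequence("GGGG", c("TA", "CA")),
                 "kept as unaligned prefix")
  expect_identical(p$prefix, "GGGG")
  expect_identical(p$blocks$copies, c(0L, 0L))
})

test_that("partition preserves content for arbitrary windows and units", {
  set.seed(99)
  unit_sets <- list(c("TA", "CA"), c("TA", "CA", "CG"),
                    c("GAA", "GAT", "GAGGAT"), "T", c("A", "CAT"))
  for (units in unit_sets) {
    wins <- random_windows(200, 0:30, c("A", "C", "G", "T", "N"))
    for (w in wins) {
      p <- suppressWarnings(partition_sequence(w, units))
      rebuilt <- paste0(p$prefix, paste0(
        strrep(p$blocks$unit, p$blocks$copies), p$blocks$unmatched,
        collapse = ""))
      expect_identical(rebuilt, w)
    }
  }
})

test_that("partition agrees with the regex decomposition oracle", {
  # exhaustive over every window up to 8 bp; longer windows are sampled
  expect_partition_matches_oracle(all_windows(0:8), c("TA", "CA"))
  set.seed(7)
  expect_partition_matches_oracle(random_windows(400, 9:20), c("TA", "CA"))
  expect_partition_matches_oracle(
    random_windows(400, 0:36, c("G", "A", "T", "C")),
    c("GAA", "GAT", "GAGGAT"))
})

test_that("assemble_blocks pads each unit field to the longest run", {
  units <- c("TA", "CA")
  parts <- lapply(c("TATACACACA", "TATATACACA"), partition_sequence,
                  units = units)
  rows <- assemble_blocks(parts, units)
  expect_identical(as.character(rows), c("TATA--CACACA", "TATATACACA--"))
  expect_identical(attr(rows, "width"), 12L)

  # interrupting residues are right-aligned: the gap sits at the
  # slippage site, before the imperfection
  parts <- lapply(c("TATAG", "TATA"), partition_sequence, units = "TA")
  expect_identical(as.character(assemble_blocks(parts, "TA")),
                   c("TATAG", "TATA-"))

  # a single sequence is its own maximum everywhere
  p <- partition_sequence("TATAGCACA", units)
  expect_identical(as.character(assemble_blocks(list(p), units)),
                   "TATAGCACA")

  expect_error(assemble_blocks(list(), units),
               class = "ssralign_argument_error")
})

test_that("realign rewrites only the SSR window and keeps content", {
  aln <- alignment(c(x = "GGTATACACAGG", y = "GGTATATACAGG"))
  out <- realign(aln, ssr_spec("TA CA", 3, 10))
  expect_identical(out$rows, c("GGTATA--CACAGG", "GGTATATACA--GG"))
  expect_identical(out$length, 14L)
  expect_identical(attr(out, "ssr_window"), c(first = 3L, last = 12L))
  expect_identical(degap(out$rows), degap(aln$rows))

  expect_error(realign(aln, ssr_spec("TA", 3, 13)),
               class = "ssralign_bounds_error")
})

test_that("realign is a fixed point on its own output", {
  set.seed(1203)
  for (case in c("A", "B", "D")) {
    panel <- slippage_panel(case, seed = sample.int(1e6, 1))
    run1 <- realign_panel(panel)
    w <- attr(run1$realigned, "ssr_window")
    again <- realign(run1$realigned,
                     ssr_spec(panel$cfg$units, w[["first"]], w[["last"]]))
    expect_identical(again$rows, run1$realigned$rows)
  }
})

test_that("realigned rows satisfy the shape formula and field purity", {
  set.seed(515)
  for (rep in 1:6) {
    case <- sample(c("B", "C", "D", "E"), 1)
    panel <- slippage_panel(case, seed = sample.int(1e6, 1))
    naive <- naive_overlap_alignment(panel)
    w <- attr(naive, "ssr_window")
    units <- panel$cfg$units
    out <- suppressWarnings(
      realign(naive, ssr_spec(units, w[["first"]], w[["last"]])))

    parts <- lapply(degap(substr(naive$rows, w[["first"]], w[["last"]])),
                    function(x) suppressWarnings(partition_sequence(x, units)))
    lay <- field_layout(parts, units)
    expect_identical(out$length,
                     (w[["first"]] - 1L) + lay$width +
                       (naive$length - w[["last"]]))
    expect_identical(degap(out$rows), panel$seqs)

    window_rows <- substr(out$rows, w[["first"]],
                          w[["first"]] - 1L + lay$width)
    expect_no_unit_overlap(window_rows, parts, units)
  }
})

test_that("ssr_fraction computes a rounded percentage and rejects bad input", {
  expect_identical(ssr_fraction(100, 100), 100)
  expect_identical(ssr_fraction(1, 3), 33.3)
  expect_error(ssr_fraction(0, 10), class = "ssralign_argument_error")
  expect_error(ssr_fraction(11, 10), class = "ssralign_argument_error")
})
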