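#' Describe an SSR locus within an alignment
#'
#' Bundles the ordered repeat units of a (possibly compound) SSR with the
#' 1-based inclusive column range `[first, last]` of the alignment that
#' contains it. Units are 1-6 bp words over `A, C, G, T` — the repeat
#' period range that defines a microsatellite. Two identical consecutive
#' units would describe a single longer run and are rejected.
#'
#' @param units Character vector of repeat units in locus order, or a
#'   single space-separated string such as `"TA CA"`.
#' @param first,last 1-based inclusive first and last alignment column of
#'   the SSR window.
#' @return An object of class `ssr_spec`.
#' @examples
#' ssr_spec("TA CA", first = 3, last = 10)
#' @export
ssr_spec <- function(units, first, last) {
  if (length(units) == 1L && grepl("[ \t]", units)) {
    units <- strsplit(trimws(units), "[ \t]+")[[1L]]
  }
  units <- toupper(as.character(units))
  if (length(units) == 0L || any(!nzchar(units))) {
    abort_ssr("at least one non-empty repeat unit is required",
              "ssralign_argument_error")
  }
  if (any(nchar(units) > 6L)) {
    abort_ssr("repeat units are at most 6 bp (microsatellite period 1-6)",
              "ssralign_argument_error")
  }
  if (any(grepl("[^ACGT]", units))) {
    abort_ssr("repeat units must be over the alphabet A, C, G, T",
              "ssralign_argument_error")
  }
  if (length(units) > 1L &&
      any(units[-1L] == units[-length(units)])) {
    abort_ssr("adjacent identical units describe one run; merge them",
              "ssralign_argument_error")
  }
  first <- as.integer(first); last <- as.integer(last)
  if (length(first) != 1L || length(last) != 1L || is.na(first) || is.na(last)) {
    abort_ssr("`first` and `last` must be single integers",
              "ssralign_argument_error")
  }
  if (first < 1L || last < first) {
    abort_ssr(sprintf("need 1 <= first <= last, got first=%d last=%d",
                      first, last),
              "ssralign_bounds_error")
  }
  structure(list(units = units, first = first, last = last),
            class = "ssr_spec")
}

#' @export
print.ssr_spec <- function(x, ...) {
  cat(sprintf("ssr_spec: units [%s], window columns %d-%d\n",
              paste(x$units, collapse = " "), x$first, x$last))
  invisible(x)
}

#' Remove gap characters from a sequence
#'
#' @param seq Character vector of (possibly gapped) sequences.
#' @return The sequences with every `-` removed, residue order preserved.
#' @examples
#' degap("TA--TA")
#' @export
degap <- function(seq) gsub("-", "", seq, fixed = TRUE)

#' Count the tandem run of a repeat unit at a position
#'
#' Returns the maximal `k >= 0` such that the subsequence of `seq`
#' starting at `pos` begins with `k` consecutive copies of `unit`. The
#' scan is greedy and stops at the first non-copy; it never looks past
#' the run.
#'
#' @param seq Ungapped sequence.
#' @param pos 1-based start position (`len(seq) + 1` is allowed and
#'   yields 0).
#' @param unit Repeat unit.
#' @return Integer copy count.
#' @examples
#' match_run("TATATACA", 1, "TA")  # 3
#' @export
match_run <- function(seq, pos, unit) {
  n <- nchar(seq); w <- nchar(unit)
  if (pos < 1L || pos > n + 1L) {
    abort_ssr(sprintf("position %d outside sequence of length %d", pos, n),
              "ssralign_bounds_error")
  }
  k <- 0L
  while (pos + w - 1L <= n && substr(seq, pos, pos + w - 1L) == unit) {
    k <- k + 1L
    pos <- pos + w
  }
  k
}

#' Partition an ungapped SSR window by repeat unit
#'
#' Decomposes a window into a prefix (residues before the first copy of
#' the first unit) followed by one block per unit: the tandem run of that
#' unit and the unmatched residues that follow it, up to the first copy of
#' the next unit. The scan is a single greedy left-to-right pass: once a
#' run is interrupted, later copies of the same unit (before the next unit
#' begins) are treated as unmatched — interrupting residues of an
#' imperfect repeat, not a resumed run. `N` matches no unit. No residue is
#' created or lost: `prefix` plus the block contents concatenate back to
#' the window.
#'
#' @param window Ungapped sequence over `A, C, G, T, N` (gaps, if present,
#'   are removed first).
#' @param units Ordered repeat units (or an `ssr_spec`).
#' @return An object of class `partitioned_ssr`: list with `prefix`
#'   (string) and `blocks`, a tibble with columns `unit`, `copies`,
#'   `unmatched`.
#' @examples
#' partition_sequence("TATAGCACA", c("TA", "CA"))
#' @export
partition_sequence <- function(window, units) {
  if (inherits(units, "ssr_spec")) units <- units$units
  units <- ssr_spec(units, 1L, 1L)$units  # reuse unit validation
  window <- degap(toupper(window))
  if (grepl("[^ACGTN]", window)) {
    abort_ssr("window contains characters outside A, C, G, T, N",
              "ssralign_alphabet_error")
  }
  n <- nchar(window)
  k <- length(units)
  # starts[[b]][p]: a full copy of unit b begins at position p
  starts <- lapply(units, function(u) {
    w <- nchar(u)
    v <- logical(n + 1L)
    if (n >= w) {
      pos <- seq_len(n - w + 1L)
      v[pos] <- substring(window, pos, pos + w - 1L) == u
    }
    v
  })
  i <- 1L
  while (i <= n && !starts[[1L]][i]) i <- i + 1L
  prefix <- substr(window, 1L, i - 1L)
  if (n > 0L && i > n) {
    warning(sprintf(
      "unit '%s' never matches; the whole window is kept as unaligned prefix",
      units[1L]), call. = FALSE)
  }
  copies <- integer(k)
  unmatched <- character(k)
  for (b in seq_len(k)) {
    w <- nchar(units[b])
    cb <- 0L
    while (i <= n && starts[[b]][i]) {
      cb <- cb + 1L
      i <- i + w
    }
    copies[b] <- cb
    start <- i
    if (b < k) {
      while (i <= n && !starts[[b + 1L]][i]) i <- i + 1L
    } else {
      i <- n + 1L
    }
    unmatched[b] <- substr(window, start, i - 1L)
  }
  structure(
    list(prefix = prefix,
         blocks = tibble::new_tibble(
           list(unit = units, copies = copies, unmatched = unmatched),
           nrow = k)),
    class = "partitioned_ssr")
}

#' @export
print.partitioned_ssr <- function(x, ...) {
  cat(sprintf("partitioned_ssr: prefix '%s'\n", x$prefix))
  print(x$blocks)
  invisible(x)
}

#' Reassemble partitioned SSR windows into gap-padded aligned rows
#'
#' Builds the realigned SSR region from per-sequence partitions. Each
#' repeat unit gets its own column field sized to the longest run of that
#' unit across sequences; runs are left-aligned in their field and padded
#' with gaps on the right, so copy-number differences appear as terminal
#' gaps (the slippage site). Unmatched interrupting residues are
#' right-aligned against the next block — after the slippage gap and
#' before the next unit — and the prefix is right-aligned against the
#' first block for the same reason. No column ever mixes two units.
#'
#' @param parts List of [partition_sequence()] results, all against the
#'   same units.
#' @param units Ordered repeat units the parts were built with.
#' @return Character vector of equal-length gapped rows, one per part,
#'   with attribute `width` (the common row length). Degapping row `i`
#'   recovers the original window content of part `i`.
#' @export
assemble_blocks <- function(parts, units) {
  if (inherits(units, "ssr_spec")) units <- units$units
  if (length(parts) == 0L) {
    abort_ssr("no partitioned sequences to assemble", "ssralign_argument_error")
  }
  if (inherits(parts, "partitioned_ssr")) parts <- list(parts)
  ok <- vapply(parts, function(p)
    inherits(p, "partitioned_ssr") && identical(p$blocks$unit, units),
    NA)
  if (!all(ok)) {
    abort_ssr("all parts must be partitioned against the same units",
              "ssralign_argument_error")
  }
  pre <- vapply(parts, function(p) p$prefix, "")
  cp <- vapply(parts, function(p) p$blocks$copies, integer(length(units)))
  um <- vapply(parts, function(p) p$blocks$unmatched, character(length(units)))
  cp <- matrix(cp, nrow = length(units))  # units x sequences
  um <- matrix(um, nrow = length(units))
  P <- max(nchar(pre))
  C <- apply(cp, 1L, max)
  U <- apply(nchar(um), 1L, max)
  uw <- nchar(units)
  rows <- vapply(seq_along(parts), function(s) {
    piece <- paste0(strrep("-", P - nchar(pre[s])), pre[s])
    for (b in seq_along(units)) {
      piece <- paste0(
        piece,
        strrep(units[b], cp[b, s]),
        strrep("-", (C[b] - cp[b, s]) * uw[b]),
        strrep("-", U[b] - nchar(um[b, s])),
        um[b, s])
    }
    piece
  }, "")
  structure(rows, width = P + sum(C * uw + U))
}

#' Realign the SSR window of an alignment
#'
#' The core operation of the package. Columns outside the window are
#' copied verbatim; the window itself is degapped per sequence,
#' partitioned by repeat unit ([partition_sequence()]) and reassembled
#' into non-overlapping per-unit block fields ([assemble_blocks()]).
#' The output alignment usually has a different (often larger) column
#' count, but every sequence's residue content is untouched:
#' `degap(row)` is identical before and after.
#'
#' @param aln An [alignment()].
#' @param spec An [ssr_spec()] (or anything coercible via
#'   `ssr_spec(units, first, last)`).
#' @return A realigned [alignment()]. The attribute `ssr_window` holds the
#'   1-based column range now occupied by the realigned SSR region, so the
#'   call can be repeated on its own output (on which it is a fixed point).
#' @examples
#' aln <- alignment(c(x = "GGTATACACAGG", y = "GGTATATACAGG"))
#' realign(aln, ssr_spec("TA CA", 3, 10))
#' @export
realign <- function(aln, spec) {
  stopifnot(is_alignment(aln))
  if (!inherits(spec, "ssr_spec")) {
    abort_ssr("`spec` must be an ssr_spec", "ssralign_argument_error")
  }
  if (spec$last > aln$length) {
    abort_ssr(sprintf(
      "SSR window %d-%d exceeds the %d alignment columns",
      spec$first, spec$last, aln$length),
      "ssralign_bounds_error")
  }
  win <- substr(aln$rows, spec$first, spec$last)
  parts <- lapply(degap(win), partition_sequence, units = spec$units)
  mid <- assemble_blocks(parts, spec$units)
  left <- substr(aln$rows, 1L, spec$first - 1L)
  right <- substr(aln$rows, spec$last + 1L, aln$length)
  out <- alignment(paste0(left, mid, right), aln$names)
  attr(out, "ssr_window") <- c(first = spec$first,
                               last = spec$first - 1L + attr(mid, "width"))
  out
}

#' SSR fraction of a sequence
#'
#' Percentage of a sequence occupied by its SSR region, rounded to one
#' decimal place — the summary used to characterise how repeat-rich a
#' locus is.
#'
#' @param ssr_len SSR region length in bp.
#' @param total_len Total sequence length in bp.
#' @return `100 * ssr_len / total_len`, rounded to 1 decimal. Vectorised.
#' @examples
#' ssr_fraction(54, 351)  # 15.4
#' @export
ssr_fraction <- function(ssr_len, total_len) {
  if (any(ssr_len <= 0) || any(total_len <= 0) || any(ssr_len > total_len)) {
    abort_ssr("need 0 < ssr_len <= total_len", "ssralign_argument_error")
  }
  round(100 * ssr_len / total_len, 1)
}
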