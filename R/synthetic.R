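#' Configuration for a synthetic SSR allele panel
#'
#' Describes how to simulate a panel of alleles at one SSR locus: each
#' allele carries the same conserved flanks around a compound repeat whose
#' per-unit tandem copy numbers vary between alleles — the
#' insertion/deletion-style variation produced by replication slippage.
#' Optionally alleles carry one interrupting residue inside a repeat run
#' (an imperfect SSR) and point substitutions in the flanks.
#'
#' @param units Ordered repeat units (or `"TA CA"`-style string).
#' @param copy_range Per-unit inclusive copy-number range: a list of
#'   `c(min, max)` integer pairs (one per unit), or a single pair recycled
#'   to all units.
#' @param n_alleles Number of alleles in the panel (>= 2).
#' @param flank5,flank3 Conserved flanking sequences (strings over ACGT).
#' @param flank_snp_rate Per-site substitution probability in the flanks.
#' @param imperfect_rate Probability that an allele carries a single
#'   interrupting residue at a random within-run boundary.
#' @param seed Optional RNG seed; with a seed, generation is fully
#'   deterministic.
#' @return An object of class `sim_config`.
#' @seealso [case_design()] for ready-made configurations emulating
#'   typical simple/compound/imperfect locus designs.
#' @export
sim_config <- function(units, copy_range, n_alleles = 26L,
                       flank5 = "GGATCCTTGAGCTTCAAGGTACCATGCACT",
                       flank3 = "TGCAGGTCGACTCTAGAGGATCCCAAGCTT",
                       flank_snp_rate = 0, imperfect_rate = 0,
                       seed = NULL) {
  units <- ssr_spec(units, 1L, 1L)$units
  if (!is.list(copy_range)) {
    copy_range <- rep(list(copy_range), length(units))  # one pair, all units
  }
  if (length(copy_range) != length(units)) {
    abort_ssr("`copy_range` must give one (min, max) pair per unit",
              "ssralign_argument_error")
  }
  cr <- t(vapply(copy_range, function(r) as.integer(r[1:2]), integer(2L)))
  if (anyNA(cr) || any(cr < 0L) || any(cr[, 1L] > cr[, 2L])) {
    abort_ssr("copy ranges must be non-negative with min <= max",
              "ssralign_argument_error")
  }
  n_alleles <- as.integer(n_alleles)
  if (is.na(n_alleles) || n_alleles < 2L) {
    abort_ssr("a panel needs at least 2 alleles", "ssralign_argument_error")
  }
  flank5 <- toupper(flank5); flank3 <- toupper(flank3)
  if (grepl("[^ACGT]", flank5) || grepl("[^ACGT]", flank3)) {
    abort_ssr("flanks must be sequences over A, C, G, T",
              "ssralign_argument_error")
  }
  if (flank_snp_rate < 0 || flank_snp_rate > 1 ||
      imperfect_rate < 0 || imperfect_rate > 1) {
    abort_ssr("rates must be probabilities in [0, 1]",
              "ssralign_argument_error")
  }
  structure(list(units = units, copy_range = cr, n_alleles = n_alleles,
                 flank5 = flank5, flank3 = flank3,
                 flank_snp_rate = flank_snp_rate,
                 imperfect_rate = imperfect_rate,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "sim_config")
}

BASES <- c("A", "C", "G", "T")

mutate_flank <- function(flank, rate) {
  sites <- which(stats::runif(nchar(flank)) < rate)
  if (!length(sites)) {
    return(list(seq = flank,
                snps = tibble::tibble(pos = integer(), base = character())))
  }
  ch <- strsplit(flank, "")[[1L]]
  new <- vapply(sites, function(p) sample(setdiff(BASES, ch[p]), 1L), "")
  ch[sites] <- new
  list(seq = paste(ch, collapse = ""),
       snps = tibble::tibble(pos = sites, base = new))
}

#' Generate a synthetic allele panel with known repeat structure
#'
#' Draws per-unit copy numbers uniformly from the configured ranges,
#' assembles each allele as `flank5 + unit1^c1 + ... + unitk^ck + flank3`,
#' then (optionally) inserts one interrupting base at a random boundary
#' inside a randomly chosen run and applies flank substitutions. The
#' returned truth record explains every emitted sequence exactly, so
#' downstream results (partitioning, realignment) can be checked against
#' the generating parameters.
#'
#' @param cfg A [sim_config()].
#' @return An object of class `allele_set`: list with `names`, `seqs`
#'   (ungapped alleles), `truth` (a tibble: `name`, `copies` list-column
#'   of per-unit counts, `imperfect` list-column, `snp5`/`snp3`
#'   list-columns) and `cfg`.
#' @examples
#' as <- generate_alleles(sim_config("TA CA", list(c(2, 2), c(3, 3)),
#'                                   n_alleles = 2, flank5 = "GG",
#'                                   flank3 = "GG", seed = 1))
#' as$seqs
#' @export
generate_alleles <- function(cfg) {
  if (!inherits(cfg, "sim_config")) {
    abort_ssr("`cfg` must be a sim_config", "ssralign_argument_error")
  }
  if (!is.null(cfg$seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(cfg$seed)
  }
  k <- length(cfg$units)
  names <- sprintf("allele%02d", seq_len(cfg$n_alleles))
  seqs <- character(cfg$n_alleles)
  copies_l <- vector("list", cfg$n_alleles)
  imperfect_l <- vector("list", cfg$n_alleles)
  snp5_l <- vector("list", cfg$n_alleles)
  snp3_l <- vector("list", cfg$n_alleles)
  for (a in seq_len(cfg$n_alleles)) {
    # sample() on a length-1 vector would draw from 1:n; draw by offset
    copies <- vapply(seq_len(k), function(i)
      cfg$copy_range[i, 1L] - 1L +
        sample.int(cfg$copy_range[i, 2L] - cfg$copy_range[i, 1L] + 1L, 1L),
      0L)
    runs <- vapply(seq_len(k), function(i) strrep(cfg$units[i], copies[i]), "")
    imperfect <- NULL
    if (cfg$imperfect_rate > 0 && stats::runif(1L) < cfg$imperfect_rate) {
      eligible <- which(copies >= 2L)
      if (length(eligible)) {
        u <- if (length(eligible) == 1L) eligible else sample(eligible, 1L)
        boundary <- sample(copies[u] - 1L, 1L)  # after copy `boundary`
        # a base that cannot extend the run keeps the interruption real
        base <- sample(setdiff(BASES, substr(cfg$units[u], 1L, 1L)), 1L)
        cut <- boundary * nchar(cfg$units[u])
        runs[u] <- paste0(substr(runs[u], 1L, cut), base,
                          substr(runs[u], cut + 1L, nchar(runs[u])))
        imperfect <- tibble::tibble(unit_index = u, after_copy = boundary,
                                    base = base)
      }
    }
    f5 <- mutate_flank(cfg$flank5, cfg$flank_snp_rate)
    f3 <- mutate_flank(cfg$flank3, cfg$flank_snp_rate)
    seqs[a] <- paste0(f5$seq, paste(runs, collapse = ""), f3$seq)
    copies_l[[a]] <- copies
    imperfect_l[a] <- list(imperfect)  # [[<- would drop the element on NULL
    snp5_l[[a]] <- f5$snps
    snp3_l[[a]] <- f3$snps
  }
  structure(list(
    names = names, seqs = seqs,
    truth = tibble::tibble(name = names, copies = copies_l,
                           imperfect = imperfect_l,
                           snp5 = snp5_l, snp3 = snp3_l),
    cfg = cfg), class = "allele_set")
}

#' @export
print.allele_set <- function(x, ...) {
  cat(sprintf("allele_set: %d alleles, units [%s], lengths %d-%d bp\n",
              length(x$seqs), paste(x$cfg$units, collapse = " "),
              min(nchar(x$seqs)), max(nchar(x$seqs))))
  invisible(x)
}

#' Rebuild allele sequences from their truth record
#'
#' Reconstructs each sequence of an [generate_alleles()] panel from the
#' recorded copy numbers, imperfection and flank substitutions alone.
#' Used as an oracle: reconstruction must reproduce `x$seqs` exactly.
#'
#' @param x An `allele_set`.
#' @return Character vector of sequences, parallel to `x$names`.
#' @export
reconstruct_alleles <- function(x) {
  stopifnot(inherits(x, "allele_set"))
  cfg <- x$cfg
  vapply(seq_along(x$seqs), function(a) {
    tr <- x$truth[a, ]
    runs <- vapply(seq_along(cfg$units), function(i)
      strrep(cfg$units[i], tr$copies[[1L]][i]), "")
    imp <- tr$imperfect[[1L]]
    if (!is.null(imp)) {
      u <- imp$unit_index
      cut <- imp$after_copy * nchar(cfg$units[u])
      runs[u] <- paste0(substr(runs[u], 1L, cut), imp$base,
                        substr(runs[u], cut + 1L, nchar(runs[u])))
    }
    apply_snps <- function(flank, snps) {
      if (nrow(snps) == 0L) return(flank)
      ch <- strsplit(flank, "")[[1L]]
      ch[snps$pos] <- snps$base
      paste(ch, collapse = "")
    }
    paste0(apply_snps(cfg$flank5, tr$snp5[[1L]]),
           paste(runs, collapse = ""),
           apply_snps(cfg$flank3, tr$snp3[[1L]]))
  }, "")
}

#' Naively aligned allele panel (the flawed baseline)
#'
#' Aligns a panel the way a repeat-blind aligner effectively does in the
#' worst case: the variable SSR core of every allele is left-justified
#' and right-padded with gaps to the longest core. Alleles with different
#' copy numbers then share columns between copies of *different* repeat
#' units — the overlap artifact that inflates pairwise distances and that
#' [realign()] removes.
#'
#' @param x An `allele_set` (flank lengths are constant by construction).
#' @return An [alignment()]. The attribute `ssr_window` gives the 1-based
#'   column range of the padded SSR core, ready to pass to [ssr_spec()].
#' @export
naive_overlap_alignment <- function(x) {
  stopifnot(inherits(x, "allele_set"))
  f5 <- nchar(x$cfg$flank5)
  f3 <- nchar(x$cfg$flank3)
  n <- nchar(x$seqs)
  core <- substr(x$seqs, f5 + 1L, n - f3)
  w <- max(nchar(core))
  rows <- paste0(substr(x$seqs, 1L, f5),
                 core, strrep("-", w - nchar(core)),
                 substr(x$seqs, n - f3 + 1L, n))
  out <- alignment(rows, x$names)
  attr(out, "ssr_window") <- c(first = f5 + 1L, last = f5 + w)
  out
}

#' Write the truth record of a panel as a tab-separated sidecar
#'
#' One row per allele: name, comma-separated per-unit copy numbers, the
#' imperfection (as `unit_index:after_copy:base` or `.`), and flank
#' substitutions (as `pos>base` lists or `.`).
#'
#' @param x An `allele_set`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(x, path) {
  stopifnot(inherits(x, "allele_set"))
  fmt_imp <- function(imp) {
    if (is.null(imp)) "." else
      sprintf("%d:%d:%s", imp$unit_index, imp$after_copy, imp$base)
  }
  fmt_snp <- function(s) {
    if (nrow(s) == 0L) "." else
      paste(sprintf("%d>%s", s$pos, s$base), collapse = ",")
  }
  lines <- c(
    paste("name", "copies", "imperfect", "snp5", "snp3", sep = "\t"),
    vapply(seq_along(x$names), function(a) paste(
      x$names[a],
      paste(x$truth$copies[[a]], collapse = ","),
      fmt_imp(x$truth$imperfect[[a]]),
      fmt_snp(x$truth$snp5[[a]]),
      fmt_snp(x$truth$snp3[[a]]), sep = "\t"), ""))
  writeLines(lines, path)
  invisible(path)
}

#' Ready-made panel designs for typical SSR locus types
#'
#' Returns a [sim_config()] emulating one of five locus designs spanning
#' the common SSR types: a simple perfect dinucleotide locus (A), compound
#' perfect loci of two to four units (B-D), and a compound imperfect
#' trinucleotide/hexanucleotide locus (E). Copy-number ranges are centred
#' on the reference motifs (TA)10, (CA)16, (CG)14, (TG)18 and
#' (GAA)4(GAT)6(GAGGAT)3, varying by about +/- 5 copies (+/- 2 for E) to
#' mimic slippage variation among 26 alleles; the conserved flanks are
#' fixed arbitrary sequences sized so the SSR core occupies a realistic
#' fraction of the locus. Design E carries interrupting residues
#' (`imperfect_rate = 0.2`); all designs default to slippage-only
#' evolution (`flank_snp_rate = 0`).
#'
#' @param case One of `"A"`-`"E"`.
#' @param n_alleles Panel size (default 26).
#' @param seed Optional RNG seed passed into the configuration.
#' @param ... Overrides passed on to [sim_config()]
#'   (e.g. `flank_snp_rate`).
#' @return A [sim_config()].
#' @examples
#' cfg <- case_design("B", seed = 1)
#' cfg$units
#' @export
case_design <- function(case = c("A", "B", "C", "D", "E"),
                        n_alleles = 26L, seed = NULL, ...) {
  case <- match.arg(case)
  designs <- list(
    A = list(units = "TA", ranges = list(c(5L, 15L))),
    B = list(units = c("TA", "CA"),
             ranges = list(c(5L, 15L), c(11L, 21L))),
    C = list(units = c("TA", "CA", "CG"),
             ranges = list(c(5L, 15L), c(11L, 21L), c(9L, 19L))),
    D = list(units = c("TA", "CA", "CG", "TG"),
             ranges = list(c(5L, 15L), c(11L, 21L), c(9L, 19L), c(13L, 23L))),
    E = list(units = c("GAA", "GAT", "GAGGAT"),
             ranges = list(c(2L, 6L), c(4L, 8L), c(1L, 5L)))
  )
  d <- designs[[case]]
  flen <- if (case == "E") c(350L, 347L) else c(150L, 147L)
  flanks <- fixed_flanks(flen[1L], flen[2L])
  args <- list(units = d$units, copy_range = d$ranges,
               n_alleles = n_alleles,
               flank5 = flanks[1L], flank3 = flanks[2L],
               imperfect_rate = if (case == "E") 0.2 else 0,
               seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(sim_config, args)
}

# fixed pseudo-random conserved flanks, independent of the user's RNG
fixed_flanks <- function(len5, len3) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(60914L)
  c(paste(sample(BASES, len5, replace = TRUE), collapse = ""),
    paste(sample(BASES, len3, replace = TRUE), collapse = ""))
}
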