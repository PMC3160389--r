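#' @keywords internal
"_PACKAGE"

# Classed conditions so callers (and the CLI) can distinguish user/data errors.
abort_ssr <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "ssralign_error")))
}

ALN_ALPHABET <- c("A", "C", "G", "T", "N", "-")

#' Construct a multiple sequence alignment
#'
#' The central container of the package: a set of named, equal-length,
#' possibly gapped DNA sequences. Sequences are uppercased on construction,
#' `.` gap characters are normalised to `-`, and the alphabet is restricted
#' to `A, C, G, T, N, -` (`U` is rejected; the package is DNA-only).
#'
#' @param rows Character vector of aligned sequences (equal lengths).
#' @param names Sequence identifiers; taken from `names(rows)` if omitted,
#'   or generated as `seq1, seq2, ...`. Must be unique and non-empty.
#' @return An object of class `ssr_alignment`: a list with elements
#'   `names`, `rows` (parallel character vectors) and `length`
#'   (the column count).
#' @examples
#' aln <- alignment(c(a = "TA-A", b = "TATA"))
#' aln$length
#' @export
alignment <- function(rows, names = NULL) {
  if (is.null(names)) names <- base::names(rows)
  rows <- as.character(rows)
  if (length(rows) == 0L) {
    abort_ssr("an alignment needs at least one sequence", "ssralign_argument_error")
  }
  if (is.null(names)) names <- paste0("seq", seq_along(rows))
  names <- as.character(names)
  if (length(names) != length(rows)) {
    abort_ssr("`names` and `rows` differ in length", "ssralign_argument_error")
  }
  if (anyNA(rows) || anyNA(names)) {
    abort_ssr("alignment rows and names must not contain NA", "ssralign_argument_error")
  }
  if (any(!nzchar(names))) {
    abort_ssr("sequence names must be non-empty", "ssralign_argument_error")
  }
  if (anyDuplicated(names)) {
    dup <- names[duplicated(names)][1L]
    abort_ssr(sprintf("duplicated sequence name: '%s'", dup),
              "ssralign_argument_error")
  }
  rows <- gsub(".", "-", toupper(rows), fixed = TRUE)
  len <- nchar(rows[1L])
  bad_len <- which(nchar(rows) != len)
  if (length(bad_len)) {
    abort_ssr(sprintf(
      "ragged alignment: sequence '%s' has %d columns, expected %d",
      names[bad_len[1L]], nchar(rows[bad_len[1L]]), len),
      "ssralign_shape_error")
  }
  bad <- regexpr("[^ACGTN-]", rows)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1L]
    abort_ssr(sprintf(
      "illegal character '%s' in sequence '%s' at position %d (alphabet: %s)",
      substr(rows[i], bad[i], bad[i]), names[i], bad[i],
      paste(ALN_ALPHABET, collapse = "")),
      "ssralign_alphabet_error")
  }
  structure(list(names = names, rows = unname(rows), length = len),
            class = "ssr_alignment")
}

#' @export
print.ssr_alignment <- function(x, ...) {
  cat(sprintf("ssr_alignment: %d sequences x %d columns\n",
              length(x$rows), x$length))
  show <- utils::head(seq_along(x$rows), 6L)
  w <- max(nchar(x$names[show]))
  for (i in show) {
    s <- x$rows[i]
    if (nchar(s) > 60L) s <- paste0(substr(s, 1L, 57L), "...")
    cat(sprintf("  %-*s %s\n", w, x$names[i], s))
  }
  if (length(x$rows) > 6L) cat(sprintf("  ... %d more\n", length(x$rows) - 6L))
  invisible(x)
}

#' @export
length.ssr_alignment <- function(x) length(x$rows)

#' Test for the alignment class
#' @param x Object to test.
#' @return `TRUE` if `x` is an `ssr_alignment`.
#' @export
is_alignment <- function(x) inherits(x, "ssr_alignment")
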