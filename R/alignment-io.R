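#' Read a multiple sequence alignment
#'
#' Reads FASTA or the plain-text table format used for allele panels:
#' the first line holds the number of sequences and the number of columns
#' separated by any whitespace, and each following line holds a sequence
#' name, whitespace, and the sequence itself.
#'
#' With `format = "auto"` a file whose first non-blank character is `>` is
#' treated as FASTA, anything else as a table. Sequences are validated,
#' uppercased, and `.` gaps normalised to `-` (see [alignment()]).
#'
#' @param path Path to the input file.
#' @param format One of `"auto"`, `"fasta"`, `"table"`.
#' @return An [alignment()] object.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "TA-A", ">b", "TATA"), f)
#' read_alignment(f)
#' @export
read_alignment <- function(path, format = c("auto", "fasta", "table")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort_ssr(sprintf("input file not found: %s", path), "ssralign_io_error")
  }
  if (format == "auto") {
    lines <- readLines(path, warn = FALSE)
    first <- lines[nzchar(trimws(lines))][1L]
    format <- if (!is.na(first) && startsWith(trimws(first), ">")) "fasta" else "table"
  }
  if (format == "fasta") {
    x <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) abort_ssr(
                    sprintf("failed to parse FASTA '%s': %s", path, conditionMessage(e)),
                    "ssralign_format_error"))
    if (length(x) == 0L) {
      abort_ssr(sprintf("no FASTA records in '%s'", path), "ssralign_format_error")
    }
    return(alignment(as.character(x), names(x)))
  }
  read_table_alignment(path)
}

read_table_alignment <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) {
    abort_ssr(sprintf("table file '%s' has no sequence lines", path),
              "ssralign_format_error")
  }
  hdr <- strsplit(trimws(lines[1L]), "[ \t]+")[[1L]]
  n_decl <- suppressWarnings(as.integer(hdr))
  if (length(hdr) != 2L || anyNA(n_decl)) {
    abort_ssr(sprintf(
      "table header must be '<n_sequences> <n_columns>', got '%s'", lines[1L]),
      "ssralign_format_error")
  }
  body <- strsplit(trimws(lines[-1L]), "[ \t]+")
  bad <- which(lengths(body) != 2L)
  if (length(bad)) {
    abort_ssr(sprintf(
      "table line %d must be '<name> <sequence>', got '%s'",
      bad[1L] + 1L, lines[bad[1L] + 1L]),
      "ssralign_format_error")
  }
  nm <- vapply(body, `[`, "", 1L)
  sq <- vapply(body, `[`, "", 2L)
  if (length(sq) != n_decl[1L]) {
    abort_ssr(sprintf(
      "table header declares %d sequences but %d were found",
      n_decl[1L], length(sq)),
      "ssralign_format_error")
  }
  if (any(nchar(sq) != n_decl[2L])) {
    i <- which(nchar(sq) != n_decl[2L])[1L]
    abort_ssr(sprintf(
      "table header declares %d columns but sequence '%s' has %d",
      n_decl[2L], nm[i], nchar(sq[i])),
      "ssralign_format_error")
  }
  alignment(sq, nm)
}

#' Write a multiple sequence alignment
#'
#' Writes FASTA (wrapped at 70 columns) or the header+rows table format
#' accepted by [read_alignment()]. Both formats round-trip: reading a
#' written file reproduces the original alignment.
#'
#' @param aln An [alignment()] object.
#' @param path Output file path.
#' @param format `"fasta"` or `"table"`. Table names must contain no
#'   whitespace (whitespace is the field separator).
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "table")) {
  format <- match.arg(format)
  stopifnot(is_alignment(aln))
  if (format == "fasta") {
    x <- Biostrings::BStringSet(stats::setNames(aln$rows, aln$names))
    tryCatch(Biostrings::writeXStringSet(x, filepath = path, width = 70L),
             error = function(e) abort_ssr(
               sprintf("cannot write '%s': %s", path, conditionMessage(e)),
               "ssralign_io_error"))
  } else {
    if (any(grepl("[ \t]", aln$names))) {
      abort_ssr("table format cannot hold names containing whitespace",
                "ssralign_format_error")
    }
    out <- c(paste(length(aln$rows), aln$length),
             paste(aln$names, aln$rows))
    tryCatch(writeLines(out, path),
             error = function(e) abort_ssr(
               sprintf("cannot write '%s': %s", path, conditionMessage(e)),
               "ssralign_io_error"))
  }
  invisible(path)
}
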