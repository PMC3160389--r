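#' Uncorrected p-distance between two aligned sequences
#'
#' Proportion of mismatching sites among comparable sites, where a site is
#' comparable when neither sequence has a gap there (pairwise deletion).
#' With no comparable sites at all the distance is 0 with a warning.
#'
#' @param a,b Equal-length (gapped) sequences.
#' @return Proportion in `[0, 1]`.
#' @examples
#' p_distance("AC-T", "ACGT")  # gap column excluded -> 0
#' @export
p_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) {
    abort_ssr(sprintf("sequences differ in length (%d vs %d)",
                      nchar(a), nchar(b)),
              "ssralign_shape_error")
  }
  ca <- strsplit(a, "", fixed = TRUE)[[1L]]
  cb <- strsplit(b, "", fixed = TRUE)[[1L]]
  comp <- ca != "-" & cb != "-"
  if (!any(comp)) {
    warning("no comparable (gap-free in both) sites; returning 0",
            call. = FALSE)
    return(0)
  }
  mean(ca[comp] != cb[comp])
}

#' Pairwise p-distance matrix of an alignment
#'
#' @param aln An [alignment()] with at least two sequences.
#' @return Symmetric numeric matrix with zero diagonal, dimnames set to
#'   the sequence names.
#' @export
distance_matrix <- function(aln) {
  stopifnot(is_alignment(aln))
  n <- length(aln$rows)
  if (n < 2L) {
    abort_ssr("a distance matrix needs at least 2 sequences",
              "ssralign_argument_error")
  }
  chars <- matrix(unlist(strsplit(aln$rows, "", fixed = TRUE)),
                  nrow = n, byrow = TRUE)
  gap <- chars == "-"
  d <- matrix(0, n, n, dimnames = list(aln$names, aln$names))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      comp <- !gap[i, ] & !gap[j, ]
      d[i, j] <- d[j, i] <- if (!any(comp)) {
        warning(sprintf(
          "no comparable sites between '%s' and '%s'; distance set to 0",
          aln$names[i], aln$names[j]), call. = FALSE)
        0
      } else {
        mean(chars[i, comp] != chars[j, comp])
      }
    }
  }
  d
}

#' Mean pairwise distance of an alignment or distance matrix
#'
#' The overall pairwise distance: the arithmetic mean of the
#' strictly-upper-triangle entries of the p-distance matrix. This is the
#' single number used to compare an alignment before and after SSR
#' realignment — spurious substitutions created by overlapping repeat
#' units inflate it, and realignment removes them.
#'
#' @param x A symmetric distance matrix (e.g. from [distance_matrix()])
#'   or an [alignment()].
#' @return Mean pairwise distance (proportion).
#' @export
mean_pairwise_distance <- function(x) {
  if (is_alignment(x)) x <- distance_matrix(x)
  x <- as.matrix(x)
  mean(x[upper.tri(x)])
}

#' UPGMA tree from a distance matrix
#'
#' Standard unweighted pair-group agglomeration: repeatedly join the two
#' closest clusters, place the new node at half the joining distance, and
#' average cluster-to-cluster distances weighted by cluster size. Ties are
#' broken deterministically in favour of the earliest-created cluster
#' pair (singletons in input order, then merge order). The result is a
#' rooted ultrametric tree.
#'
#' @param d Symmetric distance matrix with dimnames, or a [stats::dist].
#' @return An [ape::phylo] tree; root-to-tip path lengths all equal half
#'   the final joining distance.
#' @examples
#' m <- matrix(c(0, 2, 4, 2, 0, 4, 4, 4, 0), 3, 3,
#'             dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
#' ape::write.tree(upgma(m))
#' @export
upgma <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  d <- as.matrix(d)
  labels <- rownames(d)
  n <- nrow(d)
  if (n < 2L) {
    abort_ssr("UPGMA needs at least 2 taxa", "ssralign_argument_error")
  }
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  if (anyNA(d) || any(!is.finite(d))) {
    abort_ssr("distance matrix contains NA/NaN/Inf", "ssralign_argument_error")
  }
  if (ncol(d) != n || any(abs(d - t(d)) > 1e-12)) {
    abort_ssr("distance matrix must be square and symmetric",
              "ssralign_argument_error")
  }

  D <- d
  diag(D) <- Inf
  size <- rep(1L, n)
  hc_id <- -seq_len(n)          # hclust coding: negatives = singletons
  created <- seq_len(n)         # creation rank, for deterministic ties
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  alive <- seq_len(n)

  for (step in seq_len(n - 1L)) {
    sub <- D[alive, alive, drop = FALSE]
    dmin <- min(sub)
    hit <- which(sub == dmin, arr.ind = TRUE)
    hit <- hit[hit[, 1L] < hit[, 2L], , drop = FALSE]
    # earliest-created pair wins ties
    key <- order(pmin(created[alive][hit[, 1L]], created[alive][hit[, 2L]]),
                 pmax(created[alive][hit[, 1L]], created[alive][hit[, 2L]]))
    pick <- hit[key[1L], ]
    i <- alive[min(pick)]; j <- alive[max(pick)]

    merge[step, ] <- c(hc_id[i], hc_id[j])
    height[step] <- dmin
    new_d <- (size[i] * D[i, alive] + size[j] * D[j, alive]) /
      (size[i] + size[j])
    D[i, alive] <- new_d
    D[alive, i] <- new_d
    D[i, i] <- Inf
    size[i] <- size[i] + size[j]
    hc_id[i] <- step
    created[i] <- n + step
    alive <- setdiff(alive, j)
  }

  hc <- structure(
    list(merge = merge, height = height, order = hclust_order(merge),
         labels = labels, method = "average",
         call = match.call(), dist.method = "p-distance"),
    class = "hclust")
  ape::as.phylo(hc)  # halves heights: node depth = joining distance / 2
}

# leaf ordering by left-to-right traversal of the merge tree
hclust_order <- function(merge) {
  walk <- function(k) {
    if (k < 0L) return(-k)
    c(walk(merge[k, 1L]), walk(merge[k, 2L]))
  }
  walk(nrow(merge))
}

#' Serialize a tree to Newick text
#'
#' Writes standard Newick with branch lengths, `;`-terminated. Labels
#' containing Newick metacharacters or whitespace are single-quoted
#' (internal quotes doubled), so any label round-trips through a
#' standards-compliant reader such as [ape::read.tree()].
#'
#' @param tree An [ape::phylo] tree (rooted, with edge lengths).
#' @param path Optional file to write to.
#' @return The Newick string, invisibly if `path` is given.
#' @export
write_newick <- function(tree, path = NULL) {
  if (!inherits(tree, "phylo")) {
    abort_ssr("`tree` must be a phylo object", "ssralign_argument_error")
  }
  ntip <- length(tree$tip.label)
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1L])
  quote_lab <- function(x) {
    bad <- grepl("[][(),:;'\"\t ]", x)
    x[bad] <- paste0("'", gsub("'", "''", x[bad], fixed = TRUE), "'")
    x
  }
  lab <- quote_lab(tree$tip.label)
  fmt <- function(v) sub("\\.?0+$", "", sprintf("%.10f", v))
  node_txt <- function(node) {
    if (node <= ntip) return(lab[node])
    e <- kids[[as.character(node)]]
    parts <- vapply(e, function(k) {
      paste0(node_txt(tree$edge[k, 2L]), ":", fmt(tree$edge.length[k]))
    }, "")
    paste0("(", paste(parts, collapse = ","), ")")
  }
  txt <- paste0(node_txt(ntip + 1L), ";")
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
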