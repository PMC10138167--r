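#' Pairwise p-distance matrix
#'
#' Aligns every pair of sequences globally and computes the p-distance: the
#' proportion of mismatched residues over columns where both sequences are
#' ungapped. Used as desk-scale plumbing for distance-based grouping of
#' family members (a stand-in for likelihood phylogenetics, which is out of
#' scope here).
#'
#' @param records Tibble with `id` and `sequence` columns (as from
#'   [read_fasta()]), at least 3 records.
#' @param scoring Alignment scoring scheme.
#' @return Symmetric numeric matrix with dimnames set to the ids.
#' @export
distance_matrix <- function(records, scoring = default_scoring()) {
  n <- nrow(records)
  if (is.null(n) || n < 3L) stop("need >= 3 sequences", call. = FALSE)
  d <- matrix(0, n, n, dimnames = list(records$id, records$id))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      aln <- align_global(records$sequence[i], records$sequence[j], scoring)
      d[i, j] <- d[j, i] <- 1 - aln$identity
    }
  }
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining on a distance matrix, via [ape::nj()]. On an
#' additive (tree-generated) metric the generating topology and branch
#' lengths are recovered exactly.
#'
#' @param d Symmetric distance matrix (>= 3 taxa) with dimnames.
#' @return An unrooted `phylo` tree (see [ape::read.tree()]).
#' @export
neighbor_joining <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 3L) stop("need >= 3 taxa", call. = FALSE)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8))) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  ape::nj(as.dist(d))
}

#' Serialize a tree to Newick
#'
#' @param tree A `phylo` object.
#' @param path Optional output path; when `NULL` the Newick string is
#'   returned.
#' @return The Newick string (invisibly when written to a file).
#' @export
write_newick <- function(tree, path = NULL) {
  if (is.null(path)) {
    ape::write.tree(tree)
  } else {
    ape::write.tree(tree, file = path)
    invisible(ape::write.tree(tree))
  }
}
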