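#' Exon-intron structure statistics
#'
#' Per-gene exon/intron counts and lengths plus cohort-level extrema.
#' Introns are the gaps between consecutive exons, so every
#' single-transcript model satisfies `introns = exons - 1`. Extremum ties
#' are broken deterministically by the first gene in input order.
#'
#' @param models List of [gene_model()] objects.
#' @return A list with:
#'   \describe{
#'     \item{per_gene}{tibble of `gene_id`, `n_exons`, `n_introns`,
#'       `exon_lengths`, `intron_lengths` (list columns).}
#'     \item{shortest_exon, longest_exon, shortest_intron, longest_intron}{
#'       each a list of `gene_id` and `length` (`NULL` when the cohort has
#'       no introns).}
#'   }
#' @export
gene_structure_stats <- function(models) {
  stopifnot(length(models) >= 1L)
  per_gene <- lapply(models, function(m) {
    stopifnot(inherits(m, "gene_model"))
    intr <- introns(m)
    tibble::tibble(
      gene_id = m$gene_id,
      n_exons = nrow(m$exons),
      n_introns = nrow(intr),
      exon_lengths = list(as.integer(m$exons$end - m$exons$start + 1L)),
      intron_lengths = list(as.integer(intr$end - intr$start + 1L)))
  })
  per_gene <- do.call(rbind, per_gene)

  extremum <- function(lengths_col, which_fun) {
    vals <- unlist(per_gene[[lengths_col]])
    if (!length(vals)) return(NULL)
    per <- vapply(per_gene[[lengths_col]], function(v) {
      if (length(v)) which_fun(v) else NA_integer_
    }, numeric(1))
    target <- which_fun(vals)
    idx <- which(per == target)[1L]  # tie-break: first gene in input order
    list(gene_id = per_gene$gene_id[idx], length = as.integer(target))
  }
  list(per_gene = per_gene,
       shortest_exon = extremum("exon_lengths", min),
       longest_exon = extremum("exon_lengths", max),
       shortest_intron = extremum("intron_lengths", min),
       longest_intron = extremum("intron_lengths", max))
}
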