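#' Find NPA motifs in a protein sequence
#'
#' Scans with the degenerate loop-B/loop-E grammar `N-P-[A/S/T/L/V/I]`
#' (asparagine-proline followed by the alanine position, which tolerates
#' S, T, L, V or I substitutions). When the scan yields fewer than two hits
#' and a template is supplied, the template-mapped NPA columns are used as a
#' fallback to recover heavily degenerate triplets (e.g. `SLV`, `SPA`) that
#' escape the grammar.
#'
#' The first reported motif is labelled loop `B`, the second loop `E`.
#'
#' @param seq Amino-acid sequence.
#' @param pattern Regular expression for the motif grammar.
#' @param template Optional [position_template()] enabling the fallback.
#' @param scoring Alignment scoring used by the fallback mapping.
#' @return A tibble with columns `loop` (`B`, `E`, or `NA` beyond the second
#'   hit), `start` (0-based) and `triplet`. Zero rows when nothing is found.
#' @export
#' @examples
#' find_npa_motifs("GGNPAGGGGGGNPAGG")
find_npa_motifs <- function(seq, pattern = "NP[ASTLVI]", template = NULL,
                            scoring = default_scoring()) {
  seq <- check_protein_seq(seq)
  m <- gregexpr(pattern, seq)[[1]]
  hits <- if (m[1] == -1L) integer() else as.integer(m) - 1L
  if (length(hits) < 2L && !is.null(template)) {
    mapped <- map_template_positions(seq, template, scoring)
    starts <- c(mapped$query_pos[mapped$feature == "npa1_1"],
                mapped$query_pos[mapped$feature == "npa2_1"])
    starts <- starts[!is.na(starts)]
    starts <- starts[starts + 3L <= nchar(seq)]
    hits <- sort(unique(c(hits, starts)))
  }
  if (!length(hits)) {
    return(tibble::tibble(loop = character(), start = integer(),
                          triplet = character()))
  }
  hits <- sort(hits)
  # Drop overlapping follow-up hits so motif pairs never overlap.
  keep <- Reduce(function(acc, h) {
    if (!length(acc) || h >= acc[length(acc)] + 3L) c(acc, h) else acc
  }, hits, accumulate = FALSE, init = integer())
  loops <- rep(NA_character_, length(keep))
  if (length(keep) >= 1L) loops[1L] <- "B"
  if (length(keep) >= 2L) loops[2L] <- "E"
  tibble::tibble(loop = loops, start = keep,
                 triplet = substring(seq, keep + 1L, keep + 3L))
}
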