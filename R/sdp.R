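#' Count SDP mismatches against a substrate consensus
#'
#' Compares a 9-residue SDP vector with the allowed-residue sets of one
#' substrate consensus and reports every position whose residue falls
#' outside its set — the positions a printed table would mark as deviations.
#'
#' @param residues Character vector of 9 residues (SDP1..SDP9), or a
#'   one-row slice of the `vectors` tibble from [load_sdp_tables()].
#' @param consensus An [sdp_consensus()].
#' @return A list with `mismatches` (integer 0-9) and `positions`
#'   (character vector such as `"SDP3"`, in SDP order).
#' @export
#' @examples
#' sdp <- load_sdp_tables()
#' v <- sdp$vectors[sdp$vectors$protein == "PruavTIP2;1" &
#'                  sdp$vectors$substrate == "ammonia", ]
#' count_sdp_mismatches(v, sdp$consensus$ammonia)
count_sdp_mismatches <- function(residues, consensus) {
  stopifnot(inherits(consensus, "sdp_consensus"))
  if (is.data.frame(residues)) {
    if ("substrate" %in% names(residues) &&
        residues$substrate[1L] != consensus$substrate) {
      stop("vector substrate context '", residues$substrate[1L],
           "' does not match consensus '", consensus$substrate, "'",
           call. = FALSE)
    }
    residues <- unlist(residues[1L, paste0("sdp", 1:9)], use.names = FALSE)
  }
  if (length(residues) != 9L) {
    stop("SDP vector arity mismatch: expected 9 residues, got ",
         length(residues), call. = FALSE)
  }
  miss <- vapply(1:9, function(i) {
    !residues[i] %in% consensus$allowed[[i]]
  }, logical(1))
  list(mismatches = sum(miss), positions = paste0("SDP", which(miss)))
}

#' Infer transported substrates from SDP vectors
#'
#' Scores every SDP vector against the consensus for its substrate context
#' and calls it `classified` when the mismatch count does not exceed the
#' tolerance. The default tolerance 0 is the strict reading — a residue
#' vector must sit entirely inside the allowed sets. The mismatch count and
#' positions are always reported, so tolerant readings (1-2 substitutions,
#' as family surveys often allow in prose) can be reproduced by raising
#' `tolerance` without re-scoring.
#'
#' @param vectors Tibble of SDP vectors as returned by [load_sdp_tables()]
#'   (`protein`, `substrate`, `sdp1`..`sdp9`).
#' @param consensi Named list of [sdp_consensus()] objects keyed by
#'   substrate.
#' @param tolerance Integer in 0..9; per-substrate named vector also
#'   accepted (unnamed substrates default to 0).
#' @return A tibble with `protein`, `substrate`, `mismatches`,
#'   `mismatch_positions` (comma-joined), and `classified`.
#' @export
infer_substrates <- function(vectors, consensi, tolerance = 0L) {
  if (any(tolerance < 0L) || any(tolerance > 9L)) {
    stop("tolerance must lie in [0, 9]", call. = FALSE)
  }
  tol_for <- function(substrate) {
    if (!is.null(names(tolerance))) {
      if (substrate %in% names(tolerance)) {
        tolerance[[substrate]]
      } else {
        0L
      }
    } else {
      tolerance[[1L]]
    }
  }
  rows <- lapply(seq_len(nrow(vectors)), function(i) {
    v <- vectors[i, ]
    cons <- consensi[[v$substrate]]
    if (is.null(cons)) {
      stop("no consensus for substrate '", v$substrate, "'", call. = FALSE)
    }
    res <- count_sdp_mismatches(v, cons)
    tibble::tibble(
      protein = v$protein, substrate = v$substrate,
      mismatches = res$mismatches,
      mismatch_positions = paste(res$positions, collapse = ","),
      classified = res$mismatches <= tol_for(v$substrate))
  })
  do.call(rbind, rows)
}
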