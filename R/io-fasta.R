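#' Read protein or promoter sequences from FASTA
#'
#' Thin wrapper around [Biostrings::readBStringSet()] enforcing the package's
#' record contracts: unique identifiers, uppercase sequences, order preserved.
#' The identifier is the first whitespace-delimited token of each header.
#'
#' @param path Path to a FASTA file.
#' @param type `"protein"` (validates against the canonical amino-acid
#'   alphabet plus the `X` wildcard) or `"dna"` (validates against
#'   `A,C,G,T,N`).
#' @return A tibble with columns `id` and `sequence`, one row per record.
#' @export
read_fasta <- function(path, type = c("protein", "dna")) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("FASTA parse error in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(set) == 0L) {
    warning("empty FASTA file: ", path, call. = FALSE)
    return(tibble::tibble(id = character(), sequence = character()))
  }
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop("duplicate FASTA id(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  seqs <- toupper(as.character(set))
  if (type == "protein") {
    for (i in seq_along(seqs)) {
      check_protein_seq(seqs[[i]], what = paste0("record '", ids[[i]], "'"))
    }
  } else {
    bad <- vapply(seqs, function(s) {
      any(!seq_chars(s) %in% c("A", "C", "G", "T", "N"))
    }, logical(1))
    if (any(bad)) {
      stop("non-ACGTN characters in record(s): ",
           paste(ids[bad], collapse = ", "), call. = FALSE)
    }
  }
  tibble::tibble(id = unname(ids), sequence = unname(seqs))
}

#' Write sequence records to FASTA
#'
#' @param records A data frame with columns `id` and `sequence` (as returned
#'   by [read_fasta()]).
#' @param path Output file path.
#' @param width Line width for wrapping sequence bodies.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  stopifnot(is.data.frame(records),
            all(c("id", "sequence") %in% names(records)))
  set <- Biostrings::BStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

#' Read promoter sequences
#'
#' Reads a DNA FASTA of promoter windows (upstream-of-ATG sequences) and
#' enforces the promoter contract: at most 2000 bp per record — the window
#' size used when extracting promoters genome-wide.
#'
#' @param path Path to a DNA FASTA file.
#' @return A tibble with columns `gene_id` and `sequence`.
#' @export
read_promoters <- function(path) {
  rec <- read_fasta(path, type = "dna")
  too_long <- nchar(rec$sequence) > 2000L
  if (any(too_long)) {
    stop("promoter record(s) exceed the 2000 bp window: ",
         paste(rec$id[too_long], collapse = ", "), call. = FALSE)
  }
  tibble::tibble(gene_id = rec$id, sequence = rec$sequence)
}
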