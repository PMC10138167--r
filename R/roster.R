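#' Load the aquaporin family roster
#'
#' Reads a tab-separated roster of aquaporin family members — one row per
#' protein with its subfamily, length, NPA I/II triplets, ar/R selectivity
#' filter, Froger's residues (P1-P5), molecular weight, isoelectric point,
#' Ka/Ks ratio, GRAVY, and carried-along lookup fields (transmembrane domain
#' count and two subcellular localization predictions). The packaged fixture
#' `pruav_roster.tsv` transcribes the published 28-member sweet cherry
#' roster.
#'
#' @param path Path to a roster TSV. Defaults to the packaged sweet cherry
#'   fixture.
#' @return A validated tibble with one row per family member.
#' @export
#' @examples
#' roster <- load_roster()
#' table(roster$subfamily)
load_roster <- function(path = aqpscan_extdata("pruav_roster.tsv")) {
  df <- utils::read.delim(path, comment.char = "#", sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("name", "subfamily", "aa_length", "npa1", "npa2", "arR",
                "localization_wp", "localization_pp", "tdp", "mw", "ip",
                "froger", "kaks", "gravy")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("roster schema error; missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- tibble::as_tibble(df[required])
  validate_roster(df)
  df
}

validate_roster <- function(df) {
  fail <- function(row, msg) {
    stop("roster validation error at row ", row, " (",
         df$name[row], "): ", msg, call. = FALSE)
  }
  if (anyDuplicated(df$name)) {
    stop("roster validation error: duplicate name(s): ",
         paste(unique(df$name[duplicated(df$name)]), collapse = ", "),
         call. = FALSE)
  }
  for (i in seq_len(nrow(df))) {
    if (!df$subfamily[i] %in% AQP_SUBFAMILIES) {
      fail(i, paste0("unknown subfamily '", df$subfamily[i], "'"))
    }
    if (!grepl(df$subfamily[i], df$name[i], fixed = TRUE)) {
      fail(i, "subfamily inconsistent with name prefix")
    }
    if (!is.finite(df$aa_length[i]) || df$aa_length[i] <= 0) {
      fail(i, "aa_length must be > 0")
    }
    if (nchar(df$npa1[i]) != 3L || nchar(df$npa2[i]) != 3L) {
      fail(i, "NPA triplets must be 3 letters")
    }
    if (nchar(df$arR[i]) != 4L) fail(i, "ar/R filter must be 4 characters")
    if (nchar(df$froger[i]) != 5L) {
      fail(i, "Froger residues must be 5 letters (P1-P5)")
    }
    if (!is.finite(df$kaks[i]) || df$kaks[i] < 0) fail(i, "kaks must be >= 0")
  }
  invisible(df)
}

#' Load SDP consensus sets and member vectors
#'
#' Reads a combined substrate specificity-determining-position (SDP) table
#' holding, per substrate, one consensus row (the allowed-residue set at each
#' of SDP1-SDP9, multi-residue sets joined with `/`) and one member row per
#' protein scored against that substrate. The packaged fixture
#' `pruav_sdp.tsv` transcribes the published sweet cherry SDP table for six
#' substrates: ammonia, boric acid, CO2, H2O2, silicic acid and urea.
#'
#' @param path Path to an SDP TSV. Defaults to the packaged fixture.
#' @return A list with elements:
#'   \describe{
#'     \item{consensus}{named list, one [sdp_consensus] per substrate —
#'       each a list of 9 character vectors of allowed residues.}
#'     \item{vectors}{tibble with columns `protein`, `substrate` and
#'       `sdp1` ... `sdp9` (one residue each).}
#'   }
#' @export
load_sdp_tables <- function(path = aqpscan_extdata("pruav_sdp.tsv")) {
  df <- utils::read.delim(path, comment.char = "#", sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  sdp_cols <- paste0("sdp", 1:9)
  required <- c("substrate", "row_type", "protein", sdp_cols)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("SDP schema error; missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(df$substrate), SDP_SUBSTRATES)
  if (length(bad)) {
    stop("unknown substrate label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  cons_rows <- df[df$row_type == "consensus", , drop = FALSE]
  consensus <- lapply(seq_len(nrow(cons_rows)), function(i) {
    sets <- lapply(sdp_cols, function(col) {
      strsplit(cons_rows[[col]][i], "/", fixed = TRUE)[[1]]
    })
    sdp_consensus(cons_rows$substrate[i], sets)
  })
  names(consensus) <- cons_rows$substrate
  mem <- df[df$row_type == "member", , drop = FALSE]
  for (col in sdp_cols) {
    n1 <- nchar(mem[[col]]) == 1L & mem[[col]] %in% AA_CANONICAL
    if (!all(n1)) {
      stop("SDP member vector residue invalid in column ", col,
           " for: ", paste(mem$protein[!n1], collapse = ", "), call. = FALSE)
    }
  }
  vectors <- tibble::as_tibble(mem[c("protein", "substrate", sdp_cols)])
  list(consensus = consensus, vectors = vectors)
}

#' Construct a per-substrate SDP consensus
#'
#' @param substrate One of `ammonia`, `boric_acid`, `co2`, `h2o2`,
#'   `silicic_acid`, `urea`.
#' @param allowed List of exactly 9 non-empty character vectors of canonical
#'   residues, ordered SDP1..SDP9.
#' @return An object of class `sdp_consensus`.
#' @export
sdp_consensus <- function(substrate, allowed) {
  if (!substrate %in% SDP_SUBSTRATES) {
    stop("unknown substrate label: ", substrate, call. = FALSE)
  }
  if (length(allowed) != 9L) {
    stop("SDP consensus schema error: expected 9 allowed-residue sets, got ",
         length(allowed), call. = FALSE)
  }
  for (i in seq_along(allowed)) {
    set <- allowed[[i]]
    if (length(set) == 0L) {
      stop("SDP consensus error: empty allowed set at SDP", i, call. = FALSE)
    }
    if (any(!set %in% AA_CANONICAL)) {
      stop("SDP consensus error: non-canonical residue at SDP", i,
           call. = FALSE)
    }
  }
  structure(list(substrate = substrate, allowed = allowed),
            class = "sdp_consensus")
}

#' @export
print.sdp_consensus <- function(x, ...) {
  cat("<sdp_consensus>", x$substrate, "\n")
  sets <- vapply(x$allowed, paste, character(1), collapse = "/")
  cat(paste0("  SDP", 1:9, ": ", sets), sep = "\n")
  invisible(x)
}
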