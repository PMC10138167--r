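#' Classify an aquaporin subfamily from its motif signature
#'
#' A deterministic decision tree over Froger's residues (P1-P5), designed so
#' that every member of the sweet cherry roster is resolved by signature
#' alone:
#' \enumerate{
#'   \item `P5 != W` — NIP (the only subfamily whose P5 departs from
#'     tryptophan, carrying I/L/V/F instead);
#'   \item `P4 = F, P5 = W` — the aquaglyceroporin-like branch: PIP when
#'     `P1` is E or Q, XIP when `P2` is C;
#'   \item `P4 = Y, P5 = W` — TIP when `P1` is T or V, otherwise SIP.
#' }
#' Signatures not resolved by the tree fall back to a nearest-reference
#' call: the subfamily whose canonical Froger+ar/R signature has the fewest
#' residue mismatches (ties broken in PIP/NIP/TIP/SIP/XIP order), flagged
#' with `confidence = "fallback"`.
#'
#' @param froger 5-letter Froger residue string (P1-P5).
#' @param arR 4-letter ar/R selectivity filter string (may contain `-` for a
#'   missing residue); consulted only by the fallback.
#' @return A list with `subfamily`, `rule_path` (ordered tests fired) and
#'   `confidence` (`"signature"` or `"fallback"`).
#' @export
#' @examples
#' classify_subfamily("QSAFW", "FHTR")$subfamily  # PIP
#' classify_subfamily("MAAYW", "AVPN")$subfamily  # SIP
classify_subfamily <- function(froger, arR = "----") {
  if (!is.character(froger) || length(froger) != 1L || nchar(froger) != 5L) {
    stop("froger must be a 5-letter string", call. = FALSE)
  }
  if (!is.character(arR) || length(arR) != 1L || nchar(arR) != 4L) {
    stop("arR must be a 4-character string", call. = FALSE)
  }
  p <- seq_chars(toupper(froger))
  path <- character()
  fire <- function(test) path <<- c(path, test)

  fire("P5 != W ?")
  if (p[5L] != "W") {
    return(list(subfamily = "NIP", rule_path = path,
                confidence = "signature"))
  }
  fire("P4 == F ?")
  if (p[4L] == "F") {
    fire("P1 in {E,Q} ?")
    if (p[1L] %in% c("E", "Q")) {
      return(list(subfamily = "PIP", rule_path = path,
                  confidence = "signature"))
    }
    fire("P2 == C ?")
    if (p[2L] == "C") {
      return(list(subfamily = "XIP", rule_path = path,
                  confidence = "signature"))
    }
  } else {
    fire("P4 == Y ?")
    if (p[4L] == "Y") {
      fire("P1 in {T,V} ?")
      if (p[1L] %in% c("T", "V")) {
        return(list(subfamily = "TIP", rule_path = path,
                    confidence = "signature"))
      }
      return(list(subfamily = "SIP", rule_path = path,
                  confidence = "signature"))
    }
  }
  fire("fallback: nearest canonical signature")
  sigs <- subfamily_signatures()
  dist <- vapply(AQP_SUBFAMILIES, function(sf) {
    ref <- seq_chars(paste0(sigs[[sf]]$froger, sigs[[sf]]$arR))
    qry <- seq_chars(paste0(toupper(froger), toupper(arR)))
    sum(ref != qry)
  }, numeric(1))
  list(subfamily = AQP_SUBFAMILIES[which.min(dist)], rule_path = path,
       confidence = "fallback")
}

#' Classify every roster member
#'
#' @param roster A roster tibble from [load_roster()].
#' @return A tibble with `name`, `subfamily` (the call), `confidence` and
#'   the roster's own label for comparison.
#' @export
classify_roster <- function(roster) {
  calls <- lapply(seq_len(nrow(roster)), function(i) {
    classify_subfamily(roster$froger[i], roster$arR[i])
  })
  tibble::tibble(
    name = roster$name,
    subfamily = vapply(calls, `[[`, character(1), "subfamily"),
    confidence = vapply(calls, `[[`, character(1), "confidence"),
    label = roster$subfamily)
}
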