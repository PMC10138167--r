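#' Physicochemical constants
#'
#' Loads the average residue masses, Kyte-Doolittle hydropathy scale and
#' Bjellqvist pKa set from the packaged YAML file (or an override with the
#' same structure), used by [compute_mw()], [compute_gravy()], [compute_pi()]
#' and [predict_tm_segments()].
#'
#' @param path YAML file path; defaults to the packaged constants.
#' @return Nested list of constants.
#' @export
physchem_constants <- local({
  cache <- list()
  function(path = aqpscan_extdata("physchem_constants.yaml")) {
    if (is.null(cache[[path]])) cache[[path]] <<- yaml::read_yaml(path)
    cache[[path]]
  }
})

strip_wildcards <- function(seq, skip_x, what) {
  chars <- seq_chars(seq)
  if (any(chars == "X")) {
    if (!skip_x) {
      stop(what, ": sequence contains wildcard 'X'; set skip_x = TRUE to ",
           "exclude wildcard positions", call. = FALSE)
    }
    chars <- chars[chars != "X"]
  }
  if (!length(chars)) stop(what, ": no scorable residues", call. = FALSE)
  chars
}

#' Grand average of hydropathy (GRAVY)
#'
#' Arithmetic mean of Kyte-Doolittle hydropathy values over all residues.
#'
#' @param seq Amino-acid sequence.
#' @param skip_x Exclude `X` wildcard positions instead of erroring.
#' @param constants Constants from [physchem_constants()].
#' @return Dimensionless mean hydropathy (bounded by the scale extremes,
#'   -4.5 to +4.5).
#' @export
compute_gravy <- function(seq, skip_x = FALSE,
                          constants = physchem_constants()) {
  seq <- check_protein_seq(seq)
  chars <- strip_wildcards(seq, skip_x, "compute_gravy")
  kd <- unlist(constants$kyte_doolittle)
  mean(kd[chars])
}

#' Molecular weight
#'
#' Sum of average residue masses plus one water, in kilodaltons — the
#' ProtParam convention.
#'
#' @inheritParams compute_gravy
#' @return Molecular weight in kDa.
#' @export
compute_mw <- function(seq, skip_x = FALSE,
                       constants = physchem_constants()) {
  seq <- check_protein_seq(seq)
  chars <- strip_wildcards(seq, skip_x, "compute_mw")
  masses <- unlist(constants$residue_mass)
  (sum(masses[chars]) + constants$water_mass) / 1000
}

# Net charge of a peptide at a given pH under the Bjellqvist pKa set.
net_charge <- function(chars, pH, pka) {
  side <- pka$side_chain
  nt_tab <- pka$nterm
  ct_tab <- pka$cterm
  first <- chars[1L]
  last <- chars[length(chars)]
  nt_pka <- if (!is.null(nt_tab[[first]])) nt_tab[[first]] else nt_tab$default
  ct_pka <- if (!is.null(ct_tab[[last]])) ct_tab[[last]] else ct_tab$default
  pos <- 1 / (1 + 10^(pH - nt_pka))
  for (res in c("H", "K", "R")) {
    n <- sum(chars == res)
    if (n) pos <- pos + n / (1 + 10^(pH - side[[res]]))
  }
  neg <- 1 / (1 + 10^(ct_pka - pH))
  for (res in c("D", "E", "C", "Y")) {
    n <- sum(chars == res)
    if (n) neg <- neg + n / (1 + 10^(side[[res]] - pH))
  }
  pos - neg
}

#' Isoelectric point
#'
#' Root of the net-charge curve as a function of pH, located by bisection to
#' a tolerance of 0.001 pH units, using the Bjellqvist pKa set (terminal pKa
#' values are residue-specific where the set defines them).
#'
#' @inheritParams compute_gravy
#' @param tol Bisection tolerance in pH units.
#' @return Isoelectric point (pH, in (0, 14)).
#' @export
compute_pi <- function(seq, skip_x = FALSE, tol = 0.001,
                       constants = physchem_constants()) {
  seq <- check_protein_seq(seq)
  chars <- strip_wildcards(seq, skip_x, "compute_pi")
  pka <- constants$pka
  lo <- 0
  hi <- 14
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (net_charge(chars, mid, pka) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Predict transmembrane segments by hydropathy
#'
#' A sliding-window hydropathy heuristic: centers whose window-averaged
#' Kyte-Doolittle value meets the threshold are extended to full windows and
#' overlapping windows are merged into maximal segments. This is a coarse
#' stand-in for model-based topology prediction and is not expected to match
#' HMM-derived domain counts.
#'
#' @param seq Amino-acid sequence (no wildcards).
#' @param window Odd window length (default 19, a typical helix span).
#' @param threshold Mean-hydropathy cutoff (default 1.6).
#' @param constants Constants from [physchem_constants()].
#' @return Tibble of `start`/`end` segment coordinates, 1-based inclusive,
#'   sorted and non-overlapping.
#' @export
predict_tm_segments <- function(seq, window = 19L, threshold = 1.6,
                                constants = physchem_constants()) {
  seq <- check_protein_seq(seq, allow_x = FALSE)
  if (window %% 2L != 1L) stop("window must be odd", call. = FALSE)
  n <- nchar(seq)
  if (window > n) stop("window exceeds sequence length", call. = FALSE)
  kd <- unlist(constants$kyte_doolittle)[seq_chars(seq)]
  cs <- cumsum(c(0, kd))
  half <- (window - 1L) %/% 2L
  centers <- (half + 1L):(n - half)
  means <- (cs[centers + half + 1L] - cs[centers - half]) / window
  hot <- centers[means >= threshold]
  if (!length(hot)) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  starts <- hot - half
  ends <- hot + half
  # Merge overlapping/adjacent windows into maximal runs.
  out_s <- starts[1L]
  out_e <- ends[1L]
  if (length(hot) > 1L) {
    for (i in 2L:length(hot)) {
      if (starts[i] <= out_e[length(out_e)] + 1L) {
        out_e[length(out_e)] <- max(out_e[length(out_e)], ends[i])
      } else {
        out_s <- c(out_s, starts[i])
        out_e <- c(out_e, ends[i])
      }
    }
  }
  tibble::tibble(start = as.integer(out_s), end = as.integer(out_e))
}

#' Full physicochemical report
#'
#' @param seq Amino-acid sequence.
#' @param skip_x Passed to the MW/GRAVY/pI calculators.
#' @param constants Constants from [physchem_constants()].
#' @return A list with `mw_kda`, `pi`, `gravy` and `tm_segments`.
#' @export
physchem_report <- function(seq, skip_x = FALSE,
                            constants = physchem_constants()) {
  list(mw_kda = compute_mw(seq, skip_x, constants),
       pi = compute_pi(seq, skip_x, constants = constants),
       gravy = compute_gravy(seq, skip_x, constants),
       tm_segments = predict_tm_segments(gsub("X", "A", seq),
                                         constants = constants))
}
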