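#' Annotate one aquaporin protein
#'
#' End-to-end motif-level annotation of a single sequence: NPA motif scan
#' (with template fallback), template-mapped ar/R, Froger and per-substrate
#' SDP residues, a subfamily call from the extracted signature, and the
#' physicochemical report.
#'
#' @param id Protein identifier.
#' @param seq Amino-acid sequence.
#' @param template A [position_template()]; when `NULL` the best-matching
#'   packaged template (highest alignment identity) is chosen.
#' @param scoring Alignment scoring scheme.
#' @return A list of class `aqp_annotation` with elements `id`,
#'   `template_subfamily`, `npa` (motif tibble), `features` (mapped feature
#'   tibble), `arR`, `froger`, `sdp` (named list of 9-residue vectors per
#'   substrate; `NA` where deleted), `subfamily_call`, `physchem`.
#' @export
annotate_protein <- function(id, seq, template = NULL,
                             scoring = default_scoring()) {
  seq <- check_protein_seq(seq)
  if (is.null(template)) {
    templates <- aqp_templates()
    idents <- vapply(templates, function(t) {
      align_global(t$reference_sequence, seq, scoring)$identity
    }, numeric(1))
    template <- templates[[which.max(idents)]]
  }
  feats <- map_template_positions(seq, template, scoring)
  get_res <- function(names) {
    setNames(feats$residue[match(names, feats$feature)], names)
  }
  arR <- get_res(c("arR_H2", "arR_H5", "arR_LE1", "arR_LE2"))
  froger <- get_res(paste0("froger_P", 1:5))
  sdp <- lapply(setNames(nm = SDP_SUBSTRATES), function(s) {
    get_res(paste0(s, "_sdp", 1:9))
  })
  arR_str <- paste(ifelse(is.na(arR), "-", arR), collapse = "")
  froger_str <- paste(ifelse(is.na(froger), "-", froger), collapse = "")
  call <- if (!anyNA(froger)) {
    classify_subfamily(froger_str, arR_str)
  } else {
    list(subfamily = NA_character_, rule_path = character(),
         confidence = "fallback")
  }
  structure(list(
    id = id,
    template_subfamily = template$subfamily,
    npa = find_npa_motifs(seq, template = template, scoring = scoring),
    features = feats,
    arR = arR_str,
    froger = froger_str,
    sdp = sdp,
    subfamily_call = call,
    physchem = physchem_report(seq, skip_x = TRUE)),
    class = "aqp_annotation")
}

#' @export
print.aqp_annotation <- function(x, ...) {
  cat("<aqp_annotation>", x$id, "\n")
  cat("  template:", x$template_subfamily,
      " call:", x$subfamily_call$subfamily,
      paste0("(", x$subfamily_call$confidence, ")"), "\n")
  trip <- paste(x$npa$triplet, collapse = "/")
  cat("  NPA:", if (nzchar(trip)) trip else "none",
      " ar/R:", x$arR, " Froger:", x$froger, "\n")
  cat(sprintf("  Mw %.2f kDa, pI %.2f, GRAVY %.3f, %d TM segment(s)\n",
              x$physchem$mw_kda, x$physchem$pi, x$physchem$gravy,
              nrow(x$physchem$tm_segments)))
  invisible(x)
}

#' Export annotations to JSON
#'
#' Serializes one or more annotations (0-based motif indices, mapped
#' features, physicochemical report) to a JSON file.
#'
#' @param annotations A single `aqp_annotation` or a list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_annotations_json <- function(annotations, path) {
  if (inherits(annotations, "aqp_annotation")) {
    annotations <- list(annotations)
  }
  payload <- lapply(annotations, function(a) {
    list(id = a$id,
         template_subfamily = a$template_subfamily,
         subfamily = a$subfamily_call$subfamily,
         confidence = a$subfamily_call$confidence,
         npa = a$npa,
         arR = a$arR,
         froger = a$froger,
         sdp = a$sdp,
         physchem = list(mw_kda = a$physchem$mw_kda,
                         pi = a$physchem$pi,
                         gravy = a$physchem$gravy,
                         tm_segments = a$physchem$tm_segments))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
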