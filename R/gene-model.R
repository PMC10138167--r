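#' Construct a gene model
#'
#' A gene model is an ordered set of exons on one strand, in the 1-based
#' inclusive coordinate convention of GFF3. Introns are derived, not stored:
#' they are the gaps between consecutive exons.
#'
#' @param gene_id Gene identifier.
#' @param strand `"+"` or `"-"`.
#' @param exons Data frame (or matrix) with columns `start` and `end`,
#'   1-based inclusive. Exons must be non-overlapping; they are sorted by
#'   start.
#' @param utr5,utr3 Optional length-2 integer vectors `(start, end)` for
#'   untranslated regions; carried for display purposes only and excluded
#'   from exon statistics.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, strand, exons, utr5 = NULL, utr3 = NULL) {
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'", call. = FALSE)
  exons <- as.data.frame(exons)
  stopifnot(all(c("start", "end") %in% names(exons)))
  exons <- exons[order(exons$start), c("start", "end"), drop = FALSE]
  exons$start <- as.integer(exons$start)
  exons$end <- as.integer(exons$end)
  if (nrow(exons) == 0L) stop("gene model needs >= 1 exon", call. = FALSE)
  if (any(exons$start > exons$end)) {
    stop("gene model validation error (", gene_id, "): exon start > end",
         call. = FALSE)
  }
  if (nrow(exons) > 1L &&
      any(exons$start[-1L] <= exons$end[-nrow(exons)])) {
    stop("gene model validation error (", gene_id, "): overlapping exons",
         call. = FALSE)
  }
  rownames(exons) <- NULL
  structure(list(gene_id = gene_id, strand = strand,
                 exons = tibble::as_tibble(exons),
                 utr5 = utr5, utr3 = utr3),
            class = "gene_model")
}

#' Derived introns of a gene model
#'
#' @param model A [gene_model()].
#' @return Tibble of intron `start`/`end` pairs (1-based inclusive); zero
#'   rows for single-exon models.
#' @export
introns <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  ex <- model$exons
  if (nrow(ex) < 2L) {
    return(tibble::tibble(start = integer(), end = integer()))
  }
  tibble::tibble(start = ex$end[-nrow(ex)] + 1L, end = ex$start[-1L] - 1L)
}

#' @export
print.gene_model <- function(x, ...) {
  cat("<gene_model>", x$gene_id, "strand", x$strand, "-",
      nrow(x$exons), "exon(s)\n")
  invisible(x)
}

#' Read gene models from GFF3
#'
#' Imports a GFF3 file via [rtracklayer::import()] and assembles one
#' [gene_model()] per gene from its `exon` features, grouped by the `Parent`
#' attribute (falling back to `ID`/`gene_id` when absent). UTR features
#' (`five_prime_UTR`, `three_prime_UTR`) are attached when present.
#'
#' @param path Path to a GFF3 file.
#' @return Named list of `gene_model` objects, ordered by first appearance.
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "gff3")
  feats <- as.data.frame(gr)
  grouping_id <- function(d) {
    if ("Parent" %in% names(d)) {
      par <- vapply(d$Parent, function(p) {
        if (length(p)) as.character(p[[1]]) else NA_character_
      }, character(1))
    } else {
      par <- rep(NA_character_, nrow(d))
    }
    if ("ID" %in% names(d)) par[is.na(par)] <- as.character(d$ID[is.na(par)])
    # Collapse transcript-level parents like "g1.t1" onto the gene id.
    sub("\\.t\\d+$", "", par)
  }
  exons <- feats[feats$type == "exon", , drop = FALSE]
  if (nrow(exons) == 0L) stop("no exon features in ", path, call. = FALSE)
  exons$gene <- grouping_id(exons)
  utrs <- feats[feats$type %in% c("five_prime_UTR", "three_prime_UTR"), ,
                drop = FALSE]
  if (nrow(utrs)) utrs$gene <- grouping_id(utrs)
  genes <- unique(exons$gene)
  models <- lapply(genes, function(g) {
    ex <- exons[exons$gene == g, , drop = FALSE]
    u5 <- u3 <- NULL
    if (nrow(utrs)) {
      g5 <- utrs[utrs$gene == g & utrs$type == "five_prime_UTR", ]
      g3 <- utrs[utrs$gene == g & utrs$type == "three_prime_UTR", ]
      if (nrow(g5)) u5 <- c(min(g5$start), max(g5$end))
      if (nrow(g3)) u3 <- c(min(g3$start), max(g3$end))
    }
    gene_model(g, as.character(ex$strand[1L]),
               data.frame(start = ex$start, end = ex$end),
               utr5 = u5, utr3 = u3)
  })
  setNames(models, genes)
}

#' Write gene models to GFF3
#'
#' @param models List of [gene_model()] objects.
#' @param path Output path.
#' @param seqid Chromosome/scaffold name written for all features.
#' @return `path`, invisibly.
#' @export
write_gene_models <- function(models, path, seqid = "chr1") {
  lines <- c("##gff-version 3")
  for (m in models) {
    span <- c(min(m$exons$start), max(m$exons$end))
    lines <- c(lines, paste(seqid, "aqpscan", "gene", span[1], span[2], ".",
                            m$strand, ".", paste0("ID=", m$gene_id),
                            sep = "\t"))
    for (i in seq_len(nrow(m$exons))) {
      lines <- c(lines, paste(seqid, "aqpscan", "exon",
                              m$exons$start[i], m$exons$end[i], ".",
                              m$strand, ".",
                              paste0("Parent=", m$gene_id), sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
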