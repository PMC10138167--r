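IUPAC_DNA <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N")

#' Load a cis-regulatory element catalog
#'
#' Reads a YAML catalog of promoter elements: each entry carries a `name`,
#' an IUPAC `consensus` string and a `both_strands` flag. The packaged
#' default covers the nine stress-related elements surveyed in plant
#' aquaporin promoters (ARE, WRE3, WUN, STRE, LTR, MBS, DRE, AT-rich,
#' TC-rich) with PlantCARE-convention consensus strings.
#'
#' @param path YAML file path; defaults to the packaged catalog.
#' @return A tibble with columns `name`, `consensus`, `both_strands`.
#' @export
load_cre_catalog <- function(path = aqpscan_extdata("cre_catalog.yaml")) {
  raw <- yaml::read_yaml(path)
  cat <- tibble::tibble(
    name = vapply(raw$elements, `[[`, character(1), "name"),
    consensus = toupper(vapply(raw$elements, `[[`, character(1),
                               "consensus")),
    both_strands = vapply(raw$elements, function(e) {
      isTRUE(e$both_strands)
    }, logical(1)))
  if (anyDuplicated(cat$name)) {
    stop("catalog config error: duplicate element names", call. = FALSE)
  }
  bad <- vapply(cat$consensus, function(x) {
    any(!seq_chars(x) %in% IUPAC_DNA)
  }, logical(1))
  if (any(bad)) {
    stop("catalog config error: non-IUPAC symbol in consensus of ",
         paste(cat$name[bad], collapse = ", "), call. = FALSE)
  }
  cat
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# All 0-based start offsets where `pattern` (IUPAC) matches `subject`
# (concrete ACGTN). Subject letters are literal, so 'N' in the subject
# never satisfies a base code.
iupac_match_starts <- function(pattern, subject) {
  if (nchar(subject) < nchar(pattern)) return(integer())
  hits <- Biostrings::matchPattern(
    Biostrings::DNAString(pattern), Biostrings::DNAString(subject),
    fixed = c(pattern = FALSE, subject = TRUE))
  as.integer(IRanges::start(hits)) - 1L
}

#' Scan a promoter for catalog elements
#'
#' Reports every match of every catalog consensus on the forward strand
#' and, for elements flagged `both_strands`, on the reverse strand. All
#' coordinates are 0-based offsets of the forward-strand leftmost base of
#' the matched window; a minus-strand hit means the element's reverse
#' complement occupies that window. `N` in the promoter never matches.
#'
#' @param gene_id Promoter identifier carried into the hits.
#' @param sequence Promoter DNA (`A,C,G,T,N`, uppercase).
#' @param catalog Catalog tibble from [load_cre_catalog()].
#' @return A tibble of hits: `gene_id`, `element`, `start` (0-based),
#'   `strand`, `matched` (the literal forward-strand substring), sorted by
#'   `start` then element name.
#' @export
scan_promoter <- function(gene_id, sequence, catalog = load_cre_catalog()) {
  sequence <- toupper(sequence)
  if (any(!seq_chars(sequence) %in% c("A", "C", "G", "T", "N"))) {
    stop("promoter must be over A,C,G,T,N", call. = FALSE)
  }
  out <- list()
  for (i in seq_len(nrow(catalog))) {
    cons <- catalog$consensus[i]
    len <- nchar(cons)
    fwd <- iupac_match_starts(cons, sequence)
    if (length(fwd)) {
      out[[length(out) + 1L]] <- tibble::tibble(
        gene_id = gene_id, element = catalog$name[i], start = fwd,
        strand = "+",
        matched = substring(sequence, fwd + 1L, fwd + len))
    }
    if (catalog$both_strands[i]) {
      rev <- iupac_match_starts(revcomp(cons), sequence)
      # A palindromic window would match both strands; report it once, on +.
      rev <- setdiff(rev, fwd)
      if (length(rev)) {
        out[[length(out) + 1L]] <- tibble::tibble(
          gene_id = gene_id, element = catalog$name[i], start = rev,
          strand = "-",
          matched = substring(sequence, rev + 1L, rev + len))
      }
    }
  }
  if (!length(out)) {
    return(tibble::tibble(gene_id = character(), element = character(),
                          start = integer(), strand = character(),
                          matched = character()))
  }
  hits <- do.call(rbind, out)
  hits[order(hits$start, hits$element), ]
}

#' Scan a set of promoters
#'
#' @param promoters Tibble with `gene_id` and `sequence` (as from
#'   [read_promoters()]).
#' @param catalog Catalog tibble.
#' @return Row-bound hits of [scan_promoter()] over all promoters.
#' @export
scan_promoters <- function(promoters, catalog = load_cre_catalog()) {
  out <- lapply(seq_len(nrow(promoters)), function(i) {
    scan_promoter(promoters$gene_id[i], promoters$sequence[i], catalog)
  })
  do.call(rbind, out)
}

#' Gene-by-element presence matrix
#'
#' @param hits Hit tibble from [scan_promoter()]/[scan_promoters()].
#' @param genes Character vector of gene ids defining the rows.
#' @param catalog Catalog tibble defining the columns.
#' @return Logical matrix, `TRUE` where a gene has at least one hit for an
#'   element.
#' @export
presence_matrix <- function(hits, genes, catalog = load_cre_catalog()) {
  unknown <- setdiff(unique(hits$gene_id), genes)
  if (length(unknown)) {
    stop("hit(s) reference unknown gene(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  m <- matrix(FALSE, length(genes), nrow(catalog),
              dimnames = list(genes, catalog$name))
  if (nrow(hits)) {
    for (i in seq_len(nrow(hits))) {
      m[hits$gene_id[i], hits$element[i]] <- TRUE
    }
  }
  m
}

#' Count genes carrying an element (or element group)
#'
#' @param matrix Presence matrix from [presence_matrix()].
#' @param elements One or more element names; a gene counts when it has any
#'   of them (so the wound pair `c("WRE3","WUN")` counts genes with at least
#'   one wound element).
#' @return Integer count of genes.
#' @export
count_genes_with_element <- function(matrix, elements) {
  unknown <- setdiff(elements, colnames(matrix))
  if (length(unknown)) {
    stop("unknown element(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  sum(apply(matrix[, elements, drop = FALSE], 1L, any))
}

#' Load a presence-list fixture
#'
#' Reads a TSV of per-gene element presence (0/1) such as the packaged
#' `cre_presence.tsv`, which transcribes the published per-element gene
#' lists for the sweet cherry aquaporin promoters.
#'
#' @param path TSV path; defaults to the packaged fixture.
#' @return Logical matrix, genes x elements.
#' @export
load_cre_presence <- function(path = aqpscan_extdata("cre_presence.tsv")) {
  df <- utils::read.delim(path, comment.char = "#", sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE]) == 1
  rownames(m) <- df$gene
  m
}
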