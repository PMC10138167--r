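DNA_BASES <- c("A", "C", "G", "T")

codon_aa <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

# Synonymous site count of one codon: per position, the fraction of the 3
# possible single-base changes that preserve the amino acid. Changes to stop
# codons count as nonsynonymous, so every codon contributes exactly 3 sites
# split between the two classes.
codon_syn_sites <- function(codon) {
  chars <- seq_chars(codon)
  aa <- codon_aa(codon)
  s <- 0
  for (pos in 1:3) {
    for (b in setdiff(DNA_BASES, chars[pos])) {
      alt <- chars
      alt[pos] <- b
      alt_aa <- codon_aa(paste(alt, collapse = ""))
      if (alt_aa != "*" && alt_aa == aa) s <- s + 1 / 3
    }
  }
  s
}

# Synonymous / nonsynonymous difference counts between two codons, averaged
# over the minimal mutational pathways (orderings of the differing
# positions). Pathways passing through a stop codon are dropped; if every
# pathway is dropped, all orderings are used with uniform weight.
codon_diff_counts <- function(c1, c2) {
  a <- seq_chars(c1)
  b <- seq_chars(c2)
  diff_pos <- which(a != b)
  if (!length(diff_pos)) return(c(sd = 0, nd = 0))
  perms <- if (length(diff_pos) == 1L) {
    list(diff_pos)
  } else {
    all_perms(diff_pos)
  }
  score_path <- function(order, allow_stop) {
    cur <- a
    sd <- nd <- 0
    for (pos in order) {
      nxt <- cur
      nxt[pos] <- b[pos]
      aa1 <- codon_aa(paste(cur, collapse = ""))
      aa2 <- codon_aa(paste(nxt, collapse = ""))
      if (!allow_stop && aa2 == "*") return(NULL)
      if (aa1 == aa2) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  }
  scored <- Filter(Negate(is.null), lapply(perms, score_path,
                                           allow_stop = FALSE))
  if (!length(scored)) {
    scored <- lapply(perms, score_path, allow_stop = TRUE)
  }
  Reduce(`+`, scored) / length(scored)
}

all_perms <- function(x) {
  if (length(x) == 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in all_perms(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

split_codons <- function(cds) {
  n <- nchar(cds)
  substring(cds, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

check_cds <- function(cds, what) {
  cds <- toupper(cds)
  if (nchar(cds) %% 3L != 0L) {
    stop(what, " length is not a multiple of 3", call. = FALSE)
  }
  if (grepl("-", cds, fixed = TRUE)) {
    stop(what, " contains gaps; supply gap-free codon-aligned CDS",
         call. = FALSE)
  }
  if (any(!seq_chars(cds) %in% DNA_BASES)) {
    stop(what, " contains non-ACGT characters", call. = FALSE)
  }
  codons <- split_codons(cds)
  stops <- which(codon_aa(codons) == "*")
  stops <- stops[stops < length(codons)]
  if (length(stops)) {
    stop(what, " contains internal stop codon(s) at codon ",
         paste(stops, collapse = ", "), call. = FALSE)
  }
  cds
}

#' Ka/Ks by the Nei-Gojobori (1986) method
#'
#' Counts synonymous and nonsynonymous sites per codon (averaged over both
#' sequences) and synonymous/nonsynonymous differences over minimal
#' mutational pathways (multi-hit codons average uniformly over pathway
#' orderings, stop-containing intermediates excluded), then applies the
#' Jukes-Cantor multiple-hit correction to both proportions.
#'
#' @param cds_a,cds_b Codon-aligned coding sequences: equal length, multiple
#'   of 3, gap-free, no internal stop codons. A trailing stop codon is
#'   permitted and counted like any codon.
#' @return A list with `ka`, `ks`, `ratio` (`NA` when `ks == 0`),
#'   `n_sites`, `s_sites`, and the raw proportions `pn`, `ps`.
#' @export
#' @examples
#' kaks_ng86("GGTACT", "GGCACT")  # one synonymous third-position change
kaks_ng86 <- function(cds_a, cds_b) {
  cds_a <- check_cds(cds_a, "cds_a")
  cds_b <- check_cds(cds_b, "cds_b")
  if (nchar(cds_a) != nchar(cds_b)) {
    stop("sequences must have equal length", call. = FALSE)
  }
  ca <- split_codons(cds_a)
  cb <- split_codons(cds_b)
  s_sites <- 0
  sd <- nd <- 0
  for (i in seq_along(ca)) {
    s_sites <- s_sites + (codon_syn_sites(ca[i]) + codon_syn_sites(cb[i])) / 2
    counts <- codon_diff_counts(ca[i], cb[i])
    sd <- sd + counts[["sd"]]
    nd <- nd + counts[["nd"]]
  }
  n_sites <- 3 * length(ca) - s_sites
  ps <- if (s_sites > 0) sd / s_sites else 0
  pn <- if (n_sites > 0) nd / n_sites else 0
  jc <- function(p, label) {
    if (p >= 0.75) {
      stop("Jukes-Cantor correction undefined: ", label,
           sprintf(" proportion %.3f >= 3/4", p), call. = FALSE)
    }
    -3 / 4 * log(1 - 4 / 3 * p)
  }
  ks <- jc(ps, "synonymous")
  ka <- jc(pn, "nonsynonymous")
  list(ka = ka, ks = ks,
       ratio = if (ks == 0) NA_real_ else ka / ks,
       n_sites = n_sites, s_sites = s_sites, pn = pn, ps = ps)
}
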