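#' Efficiency-corrected relative expression ratio (Pfaffl method)
#'
#' `ratio = e_target^dct_target / e_ref^dct_ref`, where each delta-Ct is
#' `Ct(calibrator) - Ct(sample)` for that gene and E is the amplification
#' efficiency in fold per cycle (2 = perfect doubling). With both
#' efficiencies at 2 the ratio reduces exactly to the classic `2^ddCt`.
#'
#' @param e_target,e_ref Amplification efficiencies in `(1, 2]`.
#' @param dct_target,dct_ref Delta-Ct values (cycles).
#' @return The relative expression ratio.
#' @export
#' @examples
#' pfaffl_ratio(2, 1, 2, 0)  # one extra cycle of target: 2-fold
pfaffl_ratio <- function(e_target, dct_target, e_ref, dct_ref) {
  vals <- c(e_target, dct_target, e_ref, dct_ref)
  if (any(!is.finite(vals))) {
    stop("non-finite input to pfaffl_ratio", call. = FALSE)
  }
  if (e_target <= 1 || e_target > 2 || e_ref <= 1 || e_ref > 2) {
    stop("efficiencies must lie in (1, 2]", call. = FALSE)
  }
  e_target^dct_target / e_ref^dct_ref
}

#' Build a log2 relative-expression matrix from a Ct table
#'
#' Implements the Pfaffl workflow: technical/biological replicate Ct values
#' are averaged arithmetically per (gene, sample); each gene's delta-Ct is
#' taken against the calibrator sample; the target ratio is normalized by
#' the reference gene's ratio; and log2 is applied. Undetected measurements
#' (`NA` Ct in every replicate of a cell) stay masked (`NA`) rather than
#' being imputed: the mask is data, not zero expression.
#'
#' @param ct Tibble with columns `gene`, `sample`, `replicate`, `ct`
#'   (cycles; `NA` = not detected) and optionally `efficiency` (fold per
#'   cycle, per gene; default 2).
#' @param reference_gene Id of the normalizer gene; must be detected in
#'   every sample.
#' @param calibrator Sample id whose expression defines ratio 1.
#' @return A list of class `expression_matrix`: `log2` (genes x samples,
#'   reference gene excluded), `mask` (`TRUE` where not detected), and
#'   `calibrator`.
#' @export
build_matrix <- function(ct, reference_gene, calibrator) {
  required <- c("gene", "sample", "replicate", "ct")
  missing <- setdiff(required, names(ct))
  if (length(missing)) {
    stop("Ct table missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (!"efficiency" %in% names(ct)) ct$efficiency <- 2
  bad_e <- !is.na(ct$efficiency) & (ct$efficiency <= 1 | ct$efficiency > 2)
  if (any(bad_e)) stop("efficiencies must lie in (1, 2]", call. = FALSE)
  genes <- unique(ct$gene)
  samples <- unique(ct$sample)
  if (!reference_gene %in% genes) {
    stop("reference gene '", reference_gene, "' absent from Ct table",
         call. = FALSE)
  }
  if (!calibrator %in% samples) {
    stop("calibrator sample '", calibrator, "' absent from Ct table",
         call. = FALSE)
  }
  # Mean Ct per (gene, sample); all-NA cells stay NA (not detected).
  mean_ct <- matrix(NA_real_, length(genes), length(samples),
                    dimnames = list(genes, samples))
  eff <- setNames(rep(2, length(genes)), genes)
  for (g in genes) {
    rows_g <- ct[ct$gene == g, ]
    e <- unique(rows_g$efficiency[!is.na(rows_g$efficiency)])
    if (length(e) > 1L) {
      stop("gene '", g, "' has conflicting efficiencies", call. = FALSE)
    }
    if (length(e) == 1L) eff[g] <- e
    for (s in unique(rows_g$sample)) {
      vals <- rows_g$ct[rows_g$sample == s]
      if (any(!is.na(vals))) mean_ct[g, s] <- mean(vals, na.rm = TRUE)
    }
  }
  if (any(is.na(mean_ct[reference_gene, ]))) {
    stop("reference gene '", reference_gene,
         "' is undetected in sample(s): ",
         paste(samples[is.na(mean_ct[reference_gene, ])], collapse = ", "),
         call. = FALSE)
  }
  targets <- setdiff(genes, reference_gene)
  log2m <- matrix(NA_real_, length(targets), length(samples),
                  dimnames = list(targets, samples))
  dct_ref <- mean_ct[reference_gene, calibrator] - mean_ct[reference_gene, ]
  for (g in targets) {
    if (is.na(mean_ct[g, calibrator])) {
      warning("gene '", g, "' undetected in calibrator '", calibrator,
              "'; its relative values are masked", call. = FALSE)
      next
    }
    dct <- mean_ct[g, calibrator] - mean_ct[g, ]
    ratio <- eff[g]^dct / eff[reference_gene]^dct_ref
    log2m[g, ] <- log2(ratio)
  }
  structure(list(log2 = log2m, mask = is.na(log2m), calibrator = calibrator),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("<expression_matrix>", nrow(x$log2), "gene(s) x", ncol(x$log2),
      "sample(s); calibrator:", x$calibrator, "\n")
  invisible(x)
}

#' Call up/down regulation per cell
#'
#' @param matrix An `expression_matrix` from [build_matrix()] (or a plain
#'   numeric log2 matrix).
#' @param threshold Positive log2 fold-change cutoff; default 1 (2-fold).
#'   Boundaries are closed: a value exactly at `threshold` is `up`, exactly
#'   at `-threshold` is `down`.
#' @return Character matrix of `"up"`, `"down"`, `"nc"` (no change) and
#'   `"nd"` (not detected / masked).
#' @export
call_regulation <- function(matrix, threshold = 1) {
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  m <- if (inherits(matrix, "expression_matrix")) matrix$log2 else matrix
  calls <- ifelse(is.na(m), "nd",
                  ifelse(m >= threshold, "up",
                         ifelse(m <= -threshold, "down", "nc")))
  dimnames(calls) <- dimnames(m)
  calls
}

# Pairwise-complete Euclidean distance over unmasked cells (no rescaling:
# the root of the summed squared differences over cells observed in both
# profiles).
pairwise_complete_dist <- function(m, min_shared = 2L) {
  n <- nrow(m)
  d <- matrix(NA_real_, n, n, dimnames = list(rownames(m), rownames(m)))
  diag(d) <- 0
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- !is.na(m[i, ]) & !is.na(m[j, ])
      if (sum(shared) >= min_shared) {
        d[i, j] <- d[j, i] <- sqrt(sum((m[i, shared] - m[j, shared])^2))
      }
    }
  }
  d
}

#' Hierarchically cluster expression profiles
#'
#' Average-linkage (UPGMA-style) agglomeration on a pairwise-complete
#' Euclidean distance over unmasked cells. Profiles sharing fewer than
#' `min_shared` unmasked cells with every other profile are excluded with a
#' warning. Ties in the merge order follow [stats::hclust()]'s
#' deterministic input-order behaviour.
#'
#' @param matrix An `expression_matrix` or plain numeric matrix (rows =
#'   profiles).
#' @param method Linkage passed to [stats::hclust()].
#' @param min_shared Minimum shared unmasked cells for a defined distance.
#' @return A list with the `hclust` object and `leaf_order` (row labels in
#'   dendrogram order).
#' @export
hierarchical_cluster <- function(matrix, method = "average",
                                 min_shared = 2L) {
  m <- if (inherits(matrix, "expression_matrix")) matrix$log2 else matrix
  if (nrow(m) < 2L) stop("need >= 2 profiles", call. = FALSE)
  d <- pairwise_complete_dist(m, min_shared)
  undef <- vapply(seq_len(nrow(d)), function(i) {
    all(is.na(d[i, -i]))
  }, logical(1))
  if (any(undef)) {
    warning("excluding profile(s) with no defined distances: ",
            paste(rownames(m)[undef], collapse = ", "), call. = FALSE)
    d <- d[!undef, !undef, drop = FALSE]
  }
  if (nrow(d) < 2L) stop("fewer than 2 clusterable profiles", call. = FALSE)
  hc <- stats::hclust(stats::as.dist(d), method = method)
  list(hclust = hc, leaf_order = hc$labels[hc$order])
}
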