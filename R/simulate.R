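#' @name simulate
#' @title Seeded synthetic-data generators
#' @description
#' Every input the pipeline consumes can be generated with planted ground
#' truth: aquaporin-like proteins with motifs at known coordinates,
#' promoters with planted cis-regulatory elements over motif-free
#' background, exon-intron gene models, codon-level divergent CDS pairs,
#' and Ct tables with known fold-changes. All generators are pure functions
#' of their spec (which includes the seed): the same spec yields
#' byte-identical output, and the caller's RNG stream is never disturbed.
NULL

#' Generate aquaporin-like proteins with planted motifs
#'
#' Builds one sequence per requested member from the packaged subfamily
#' template backbone: the member's NPA I/II triplets, ar/R filter, Froger
#' residues and (when available in the packaged SDP table) per-substrate
#' SDP vectors are planted at the template columns; all other positions are
#' redrawn at random; optional random insertions shift the features to
#' exercise alignment-based mapping. A `-` in the ar/R string deletes that
#' filter position from the sequence (the missing-residue case). The
#' background is scrubbed so the planted NPA motifs are the only degenerate
#' NPA matches.
#'
#' @param spec A list with fields:
#'   \describe{
#'     \item{seed}{integer seed (required).}
#'     \item{members}{tibble with columns `name`, `subfamily`, `npa1`,
#'       `npa2`, `arR`, `froger`; defaults to the packaged 28-member roster,
#'       i.e. the study's own signatures.}
#'     \item{insert_max}{maximum number of random single-residue insertions
#'       per sequence (default 5; 0 disables).}
#'     \item{spacer_mutation_rate}{per-position probability of redrawing a
#'       non-feature residue (default 0.15). Spacers diverge from the
#'       backbone at this rate, so generated members stay alignable to
#'       their subfamily template while remaining distinct.}
#'   }
#' @return A list with `records` (tibble `id`, `sequence`) and `truth`
#'   (tibble `protein`, `feature`, `pos0` 0-based, `residue`; `NA` position
#'   for deleted features).
#' @export
generate_aqp_proteins <- function(spec) {
  stopifnot(!is.null(spec$seed))
  members <- spec$members
  if (is.null(members)) members <- load_roster()
  insert_max <- if (is.null(spec$insert_max)) 5L else spec$insert_max
  mut_rate <- if (is.null(spec$spacer_mutation_rate)) {
    0.15
  } else {
    spec$spacer_mutation_rate
  }
  templates <- aqp_templates()
  layout <- template_layout()
  sdp <- load_sdp_tables()

  with_seed(spec$seed, {
    recs <- vector("list", nrow(members))
    truths <- vector("list", nrow(members))
    for (k in seq_len(nrow(members))) {
      m <- members[k, ]
      tpl <- templates[[m$subfamily]]
      chars <- seq_chars(tpl$reference_sequence)
      pos0 <- layout  # working copy of feature positions (0-based)

      plant <- function(features, residues) {
        chars[pos0[features] + 1L] <<- residues
      }
      plant(paste0("npa1_", 1:3), seq_chars(m$npa1))
      plant(paste0("npa2_", 1:3), seq_chars(m$npa2))
      arR <- seq_chars(m$arR)
      arR_feats <- c("arR_H2", "arR_H5", "arR_LE1", "arR_LE2")
      deleted <- arR_feats[arR == "-"]
      plant(arR_feats[arR != "-"], arR[arR != "-"])
      plant(paste0("froger_P", 1:5), seq_chars(m$froger))
      for (s in SDP_SUBSTRATES) {
        row <- sdp$vectors[sdp$vectors$protein == m$name &
                           sdp$vectors$substrate == s, ]
        if (nrow(row) == 1L) {
          plant(paste0(s, "_sdp", 1:9),
                unlist(row[paste0("sdp", 1:9)], use.names = FALSE))
        }
      }
      # Mutate spacers (non-feature positions) at the configured rate so
      # the member diverges from the backbone but stays alignable.
      feat_idx1 <- unname(pos0) + 1L
      spacer <- setdiff(seq_along(chars), feat_idx1)
      if (mut_rate > 0) {
        hit <- spacer[runif(length(spacer)) < mut_rate]
        chars[hit] <- sample(AA_CANONICAL, length(hit), replace = TRUE)
      }

      # Delete '-' ar/R positions, right to left so shifts stay simple.
      for (f in deleted[order(pos0[deleted], decreasing = TRUE)]) {
        del0 <- pos0[[f]]
        chars <- chars[-(del0 + 1L)]
        pos0[pos0 > del0] <- pos0[pos0 > del0] - 1L
        pos0[f] <- NA_integer_
      }

      # Random insertions in spacer gaps (never inside an NPA triplet).
      n_ins <- if (insert_max > 0L) sample(0:insert_max, 1L) else 0L
      if (n_ins > 0L) {
        forbidden <- integer()
        for (npa in c("npa1_1", "npa2_1")) {
          st <- pos0[[npa]]
          if (!is.na(st)) forbidden <- c(forbidden, st + 1:2)
        }
        for (ins in seq_len(n_ins)) {
          repeat {
            at0 <- sample(0:length(chars), 1L)  # insert before position at0
            if (!at0 %in% forbidden) break
          }
          chars <- append(chars, sample(AA_CANONICAL, 1L), after = at0)
          shift <- !is.na(pos0) & pos0 >= at0
          pos0[shift] <- pos0[shift] + 1L
          forbidden[forbidden >= at0] <- forbidden[forbidden >= at0] + 1L
        }
      }

      keep0 <- c(pos0[["npa1_1"]], pos0[["npa2_1"]])
      chars <- scrub_spurious_npa(chars, keep0[!is.na(keep0)],
                                  pos0[!is.na(pos0)])
      recs[[k]] <- tibble::tibble(id = m$name,
                                  sequence = paste(chars, collapse = ""))
      truths[[k]] <- tibble::tibble(
        protein = m$name, feature = names(pos0), pos0 = unname(pos0),
        residue = ifelse(is.na(pos0), NA_character_, chars[pos0 + 1L]))
    }
    list(records = do.call(rbind, recs), truth = do.call(rbind, truths))
  })
}

mutate_base <- function(base) {
  sample(setdiff(c("A", "C", "G", "T"), base), 1L)
}

# Draw a DNA background of the given length containing no catalog motif on
# either strand: random draw, then iteratively break any remaining hit by
# mutating its middle base.
motif_free_background <- function(length, catalog, max_iter = 200L) {
  chars <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
  for (iter in seq_len(max_iter)) {
    hits <- scan_promoter("bg", paste(chars, collapse = ""), catalog)
    if (nrow(hits) == 0L) return(chars)
    for (i in seq_len(nrow(hits))) {
      mid <- hits$start[i] + nchar(hits$matched[i]) %/% 2L + 1L
      chars[mid] <- mutate_base(chars[mid])
    }
  }
  stop("rejection sampling failed to find a motif-free background; ",
       "reduce the catalog or promoter length", call. = FALSE)
}

#' Generate promoters realizing a presence matrix
#'
#' Emits one promoter per matrix row: a motif-free random background (no
#' catalog element matches on either strand) with exactly one planted
#' instance per TRUE cell, at a random offset and (for double-stranded
#' elements) random strand. Each promoter is validated by re-scanning; if
#' planting created a spurious cross-element match the offsets are redrawn.
#'
#' @param presence Logical gene x element matrix (rownames = gene ids,
#'   colnames must exist in the catalog).
#' @param catalog Catalog tibble from [load_cre_catalog()].
#' @param spec List with `seed` (required), `length` (promoter length,
#'   default 2000) and `max_retries` (per promoter, default 20).
#' @return List with `promoters` (tibble `gene_id`, `sequence`) and `truth`
#'   (the input matrix plus a `hits` tibble of planted coordinates:
#'   `gene_id`, `element`, `start` 0-based, `strand`).
#' @export
generate_promoters <- function(presence, catalog = load_cre_catalog(),
                               spec = list(seed = 1L)) {
  stopifnot(!is.null(spec$seed))
  len <- if (is.null(spec$length)) 2000L else spec$length
  max_retries <- if (is.null(spec$max_retries)) 20L else spec$max_retries
  unknown <- setdiff(colnames(presence), catalog$name)
  if (length(unknown)) {
    stop("presence matrix references unknown element(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  with_seed(spec$seed, {
    proms <- vector("list", nrow(presence))
    hit_rows <- list()
    for (g in seq_len(nrow(presence))) {
      gene <- rownames(presence)[g]
      wanted <- colnames(presence)[presence[g, ]]
      ok <- FALSE
      for (try in seq_len(max_retries)) {
        chars <- motif_free_background(len, catalog)
        occupied <- matrix(integer(), ncol = 2)
        planted <- list()
        clash <- FALSE
        for (el in wanted) {
          row <- catalog[catalog$name == el, ]
          motif <- row$consensus
          mlen <- nchar(motif)
          strand <- if (row$both_strands && runif(1) < 0.5) "-" else "+"
          planted_seq <- if (strand == "-") revcomp(motif) else motif
          placed <- FALSE
          for (attempt in 1:50) {
            start0 <- sample(0:(len - mlen), 1L)
            overlaps <- nrow(occupied) > 0 &&
              any(start0 < occupied[, 2] & start0 + mlen > occupied[, 1])
            if (!overlaps) {
              chars[(start0 + 1L):(start0 + mlen)] <- seq_chars(planted_seq)
              occupied <- rbind(occupied, c(start0, start0 + mlen))
              planted[[length(planted) + 1L]] <- tibble::tibble(
                gene_id = gene, element = el, start = start0,
                strand = strand)
              placed <- TRUE
              break
            }
          }
          if (!placed) {
            clash <- TRUE
            break
          }
        }
        if (clash) next
        seqstr <- paste(chars, collapse = "")
        found <- scan_promoter(gene, seqstr, catalog)
        if (setequal(unique(found$element), wanted) &&
            nrow(found) == length(wanted)) {
          proms[[g]] <- tibble::tibble(gene_id = gene, sequence = seqstr)
          hit_rows <- c(hit_rows, planted)
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop("could not realize presence row for gene '", gene,
             "' within the retry budget; consider a shorter catalog or a ",
             "longer promoter", call. = FALSE)
      }
    }
    list(promoters = do.call(rbind, proms),
         truth = list(presence = presence,
                      hits = if (length(hit_rows)) {
                        do.call(rbind, hit_rows)
                      } else {
                        tibble::tibble(gene_id = character(),
                                       element = character(),
                                       start = integer(),
                                       strand = character())
                      }))
  })
}

#' Generate exon-intron gene models
#'
#' Random single-transcript gene models with exon counts spanning the range
#' seen in plant aquaporin families (1 to 5 exons, i.e. 0 to 4 introns) and
#' exon/intron lengths drawn uniformly from ranges bracketing the family's
#' printed extremes.
#'
#' @param spec List with `seed` (required), `n_genes` (default 28),
#'   `exon_counts` (default `1:5`), `exon_len` (default `c(33, 792)`),
#'   `intron_len` (default `c(91, 3450)`).
#' @return List with `models` (named list of [gene_model()]) and `truth`
#'   (tibble `gene_id`, `n_exons`, `n_introns`, list columns `exon_lengths`
#'   and `intron_lengths`).
#' @export
generate_gene_models <- function(spec) {
  stopifnot(!is.null(spec$seed))
  n_genes <- if (is.null(spec$n_genes)) 28L else spec$n_genes
  exon_counts <- if (is.null(spec$exon_counts)) 1:5 else spec$exon_counts
  exon_len <- if (is.null(spec$exon_len)) c(33L, 792L) else spec$exon_len
  intron_len <- if (is.null(spec$intron_len)) c(91L, 3450L) else spec$intron_len
  with_seed(spec$seed, {
    models <- list()
    truth <- vector("list", n_genes)
    for (i in seq_len(n_genes)) {
      gid <- sprintf("synthgene%02d", i)
      n_ex <- sample(exon_counts, 1L)
      el <- sample(exon_len[1]:exon_len[2], n_ex, replace = TRUE)
      il <- if (n_ex > 1L) {
        sample(intron_len[1]:intron_len[2], n_ex - 1L, replace = TRUE)
      } else {
        integer()
      }
      start <- sample(1:10000, 1L)
      starts <- integer(n_ex)
      ends <- integer(n_ex)
      pos <- start
      for (e in seq_len(n_ex)) {
        starts[e] <- pos
        ends[e] <- pos + el[e] - 1L
        if (e < n_ex) pos <- ends[e] + il[e] + 1L
      }
      models[[gid]] <- gene_model(gid, sample(c("+", "-"), 1L),
                                  data.frame(start = starts, end = ends))
      truth[[i]] <- tibble::tibble(gene_id = gid, n_exons = n_ex,
                                   n_introns = n_ex - 1L,
                                   exon_lengths = list(el),
                                   intron_lengths = list(il))
    }
    list(models = models, truth = do.call(rbind, truth))
  })
}

random_cds <- function(n_codons) {
  sense_codons <- names(Biostrings::GENETIC_CODE)[
    Biostrings::GENETIC_CODE != "*"]
  paste(sample(sense_codons, n_codons, replace = TRUE), collapse = "")
}

# All single-base codon variants of `codon`, annotated syn/nonsyn.
codon_variants <- function(codon) {
  chars <- seq_chars(codon)
  aa <- codon_aa(codon)
  out <- list()
  for (pos in 1:3) {
    for (b in setdiff(DNA_BASES, chars[pos])) {
      alt <- chars
      alt[pos] <- b
      alt_codon <- paste(alt, collapse = "")
      alt_aa <- codon_aa(alt_codon)
      if (alt_aa == "*") next
      out[[length(out) + 1L]] <- list(codon = alt_codon,
                                      synonymous = alt_aa == aa)
    }
  }
  out
}

#' Generate codon-aligned divergent CDS pairs
#'
#' Each pair starts from a random stop-free CDS; the partner applies a
#' controlled number of synonymous and nonsynonymous single-base changes,
#' at most one change per codon, never creating a stop. The defaults (many
#' synonymous, few nonsynonymous changes) emulate sequences under purifying
#' selection, the regime reported throughout the aquaporin family.
#'
#' @param spec List with `seed` (required), `n_pairs` (default 1),
#'   `n_codons` (default 100), `n_syn` (default 8), `n_nonsyn` (default 1).
#' @return List with `pairs` (tibble `id`, `cds_a`, `cds_b`) and `truth`
#'   (tibble `id`, `n_syn`, `n_nonsyn`).
#' @export
generate_cds_pairs <- function(spec) {
  stopifnot(!is.null(spec$seed))
  n_pairs <- if (is.null(spec$n_pairs)) 1L else spec$n_pairs
  n_codons <- if (is.null(spec$n_codons)) 100L else spec$n_codons
  n_syn <- if (is.null(spec$n_syn)) 8L else spec$n_syn
  n_nonsyn <- if (is.null(spec$n_nonsyn)) 1L else spec$n_nonsyn
  if (n_syn + n_nonsyn > n_codons) {
    stop("n_syn + n_nonsyn cannot exceed n_codons (one change per codon)",
         call. = FALSE)
  }
  with_seed(spec$seed, {
    pairs <- vector("list", n_pairs)
    truth <- vector("list", n_pairs)
    for (p in seq_len(n_pairs)) {
      repeat {
        cds_a <- random_cds(n_codons)
        codons <- split_codons(cds_a)
        available <- seq_len(n_codons)
        applied_syn <- applied_nonsyn <- 0L
        ok <- TRUE
        for (kind in c(rep("syn", n_syn), rep("nonsyn", n_nonsyn))) {
          placed <- FALSE
          for (idx in sample(available)) {
            vars <- codon_variants(codons[idx])
            vars <- Filter(function(v) v$synonymous == (kind == "syn"), vars)
            if (length(vars)) {
              pick <- vars[[sample.int(length(vars), 1L)]]
              codons[idx] <- pick$codon
              available <- setdiff(available, idx)
              if (kind == "syn") {
                applied_syn <- applied_syn + 1L
              } else {
                applied_nonsyn <- applied_nonsyn + 1L
              }
              placed <- TRUE
              break
            }
          }
          if (!placed) {
            ok <- FALSE
            break
          }
        }
        if (ok) break
      }
      pairs[[p]] <- tibble::tibble(id = sprintf("pair%03d", p),
                                   cds_a = cds_a,
                                   cds_b = paste(codons, collapse = ""))
      truth[[p]] <- tibble::tibble(id = sprintf("pair%03d", p),
                                   n_syn = applied_syn,
                                   n_nonsyn = applied_nonsyn)
    }
    list(pairs = do.call(rbind, pairs), truth = do.call(rbind, truth))
  })
}

#' Generate a qPCR Ct table with planted fold-changes
#'
#' Emulates the study's qPCR design: a reference (normalizer) gene with
#' constant expression, a calibrator sample defining ratio 1, three
#' biological x two technical replicates, and Gaussian Ct noise. Each
#' target gene's Ct in a sample is displaced from its baseline by
#' `-log2FC / log2(E)` cycles, so [build_matrix()] recovers the planted
#' log2 fold-changes exactly at `noise_sd = 0`.
#'
#' @param spec List with fields `seed` (required), `genes` (default 6
#'   synthetic genes), `samples` (default `c("control", "s1", "s2")`),
#'   `calibrator` (default first sample), `log2fc` (genes x samples matrix;
#'   default drawn uniformly from -3..3, calibrator column 0),
#'   `efficiency` (per-gene named vector or scalar, default 2), `noise_sd`
#'   (cycles, default 0.2), `n_bio` (default 3), `n_tech` (default 2),
#'   `baseline_ct` (default 24), `reference_gene` (default `"REF"`).
#' @return List with `ct` (tibble `gene`, `sample`, `replicate`, `ct`,
#'   `efficiency`), `reference_gene`, `calibrator`, and `truth` (the
#'   planted log2 fold-change matrix).
#' @export
generate_ct_table <- function(spec) {
  stopifnot(!is.null(spec$seed))
  genes <- if (is.null(spec$genes)) sprintf("synthAQP%d", 1:6) else spec$genes
  samples <- if (is.null(spec$samples)) c("control", "s1", "s2") else spec$samples
  calibrator <- if (is.null(spec$calibrator)) samples[1L] else spec$calibrator
  noise_sd <- if (is.null(spec$noise_sd)) 0.2 else spec$noise_sd
  n_bio <- if (is.null(spec$n_bio)) 3L else spec$n_bio
  n_tech <- if (is.null(spec$n_tech)) 2L else spec$n_tech
  baseline <- if (is.null(spec$baseline_ct)) 24 else spec$baseline_ct
  ref_gene <- if (is.null(spec$reference_gene)) "REF" else spec$reference_gene
  eff <- spec$efficiency
  if (is.null(eff)) eff <- 2
  if (length(eff) == 1L && is.null(names(eff))) {
    eff <- setNames(rep(eff, length(genes)), genes)
  }
  with_seed(spec$seed, {
    fc <- spec$log2fc
    if (is.null(fc)) {
      fc <- matrix(round(runif(length(genes) * length(samples), -3, 3), 2),
                   length(genes), length(samples),
                   dimnames = list(genes, samples))
    }
    fc[, calibrator] <- 0
    rows <- list()
    for (g in c(ref_gene, genes)) {
      e_g <- if (g == ref_gene) 2 else unname(eff[g])
      base_g <- baseline + runif(1, -2, 2)
      for (s in samples) {
        true_ct <- if (g == ref_gene) {
          base_g
        } else {
          base_g - fc[g, s] / log2(e_g)
        }
        for (b in seq_len(n_bio)) {
          for (t in seq_len(n_tech)) {
            rows[[length(rows) + 1L]] <- tibble::tibble(
              gene = g, sample = s,
              replicate = sprintf("b%d.t%d", b, t),
              ct = true_ct + if (noise_sd > 0) rnorm(1, 0, noise_sd) else 0,
              efficiency = e_g)
          }
        }
      }
    }
    list(ct = do.call(rbind, rows), reference_gene = ref_gene,
         calibrator = calibrator, truth = fc)
  })
}
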