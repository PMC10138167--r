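scoring <- default_scoring()

test_that("self-alignment scores the diagonal and empty input errors", {
  s <- "NPAVTWGH"
  aln <- align_global(s, s, scoring)
  diag_score <- sum(vapply(seq_chars(s), function(r) {
    scoring$matrix[r, r]
  }, numeric(1)))
  expect_equal(aln$score, diag_score)
  expect_equal(aln$identity, 1)
  expect_error(align_global("A", ""), "non-empty")
  expect_error(align_global("ABZ", "AA"), "non-canonical")
})

test_that("alignment score equals exhaustive enumeration on short pairs", {
  set.seed(101)
  for (rep in 1:12) {
    a <- random_protein(sample(2:7, 1))
    b <- random_protein(sample(2:7, 1))
    expect_equal(
      align_global(a, b, scoring)$score,
      enum_align_score(a, b, scoring$matrix, scoring$gap_open,
                       scoring$gap_extend),
      info = paste(a, b))
  }
})

test_that("alignment score is symmetric under the symmetric matrix", {
  set.seed(7)
  for (rep in 1:10) {
    a <- random_protein(sample(5:40, 1))
    b <- random_protein(sample(5:40, 1))
    expect_equal(align_global(a, b)$score, align_global(b, a)$score)
  }
})

test_that("template mapping is the identity on the reference itself", {
  tpl <- aqp_templates()$PIP
  mapped <- map_template_positions(tpl$reference_sequence, tpl)
  expect_equal(mapped$query_pos, mapped$ref_pos)
  ref_chars <- seq_chars(tpl$reference_sequence)
  expect_equal(mapped$residue, ref_chars[mapped$ref_pos + 1L])
})

test_that("template mapping tracks planted insertions and deletions", {
  tpl <- aqp_templates()$PIP
  ref <- tpl$reference_sequence
  h2 <- tpl$columns[["arR_H2"]]
  # five residues inserted upstream of arR_H2 shift it (and everything
  # downstream) by +5
  ins <- paste0(substring(ref, 1, h2 - 10), "WWWWW",
                substring(ref, h2 - 9))
  mapped <- map_template_positions(ins, tpl)
  expect_equal(mapped$query_pos[mapped$feature == "arR_H2"], h2 + 5L)
  up <- mapped$feature[mapped$ref_pos < h2 - 10]
  expect_equal(mapped$query_pos[mapped$feature %in% up],
               mapped$ref_pos[mapped$feature %in% up])

  # deletion spanning froger_P2 leaves that feature missing, others mapped
  p2 <- tpl$columns[["froger_P2"]]
  del <- paste0(substring(ref, 1, p2 - 1), substring(ref, p2 + 3))
  mapped <- map_template_positions(del, tpl)
  expect_true(is.na(mapped$query_pos[mapped$feature == "froger_P2"]))
  expect_equal(mapped$query_pos[mapped$feature == "froger_P1"],
               tpl$columns[["froger_P1"]])
  expect_equal(mapped$query_pos[mapped$feature == "froger_P5"],
               tpl$columns[["froger_P5"]] - 3L)
})

test_that("template mapping refuses low-identity queries", {
  tpl <- aqp_templates()$PIP
  set.seed(5)
  expect_error(
    map_template_positions(strrep("G", 280), tpl, min_identity = 0.6),
    "identity")
})

test_that("canonical NPA pairs are found and labelled loop B then E", {
  hits <- find_npa_motifs("GGGGNPAGGGGGGGGGGNPAGGG")
  expect_equal(hits$loop, c("B", "E"))
  expect_equal(hits$triplet, c("NPA", "NPA"))
  expect_equal(hits$start, c(4L, 17L))
  expect_lt(hits$start[1], hits$start[2])
})

test_that("degenerate XIP-like NPA motifs are recovered via the template", {
  tpl <- aqp_templates()$XIP
  gen <- generate_aqp_proteins(list(
    seed = 33L, insert_max = 0L,
    members = tibble::tibble(name = "synthXIP", subfamily = "XIP",
                             npa1 = "SLV", npa2 = "SPA", arR = "VIVR",
                             froger = "MCAFW")))
  seq <- gen$records$sequence[1]
  hits <- find_npa_motifs(seq, template = tpl)
  expect_equal(hits$triplet[1:2], c("SLV", "SPA"))
  truth <- gen$truth
  expect_equal(hits$start[1],
               truth$pos0[truth$feature == "npa1_1"])
  expect_equal(hits$start[2],
               truth$pos0[truth$feature == "npa2_1"])
})

test_that("planted NPA motifs are recovered exactly across random seeds", {
  roster <- load_roster()
  canonical <- roster[roster$npa1 == "NPA" & roster$npa2 == "NPA", ]
  for (seed in 1:100) {
    member <- canonical[(seed %% nrow(canonical)) + 1L, ]
    gen <- generate_aqp_proteins(list(seed = seed, members = member,
                                      insert_max = 8L))
    hits <- find_npa_motifs(gen$records$sequence[1])
    truth <- gen$truth
    expect_equal(hits$start[hits$loop == "B"],
                 truth$pos0[truth$feature == "npa1_1"],
                 info = paste("seed", seed))
    expect_equal(hits$start[hits$loop == "E"],
                 truth$pos0[truth$feature == "npa2_1"],
                 info = paste("seed", seed))
  }
})

test_that("motif pairs never overlap and keep loop order", {
  set.seed(99)
  philic <- c("D", "E", "K", "Q", "R")
  for (rep in 1:25) {
    triplets <- sample(c("NPA", "NPS", "NPT", "NPV", "NPL", "NPI"),
                       sample(2:4, 1), replace = TRUE)
    parts <- character()
    for (t in triplets) {
      parts <- c(parts,
                 paste(sample(philic, sample(0:20, 1), TRUE), collapse = ""),
                 t)
    }
    seq <- paste(c(parts,
                   paste(sample(philic, 10, TRUE), collapse = "")),
                 collapse = "")
    hits <- find_npa_motifs(seq)
    expect_equal(nrow(hits), length(triplets))
    expect_true(all(diff(hits$start) >= 3))
    expect_equal(hits$loop[1:2], c("B", "E"))
    expect_lt(hits$start[which(hits$loop == "B")],
              hits$start[which(hits$loop == "E")])
  }
})

test_that("GRAVY matches the scale on single residues and is length-linear", {
  expect_equal(compute_gravy("GG"), -0.4)
  expect_equal(compute_gravy("I"), 4.5)
  s1 <- "IVLF"
  s2 <- "DEKRNQ"
  expect_equal(compute_gravy(paste0(s1, s2)),
               (4 * compute_gravy(s1) + 6 * compute_gravy(s2)) / 10)
  # hand-summed full scale over the 20 distinct residues
  full <- "ARNDCEQGHILKMFPSTWYV"
  kd_sum <- 1.8 - 4.5 - 3.5 - 3.5 + 2.5 - 3.5 - 3.5 - 0.4 - 3.2 + 4.5 +
    3.8 - 3.9 + 1.9 + 2.8 - 1.6 - 0.8 - 0.7 - 0.9 - 1.3 + 4.2
  expect_equal(compute_gravy(full), kd_sum / 20)
  expect_error(compute_gravy("GXG"), "wildcard")
  expect_equal(compute_gravy("GXG", skip_x = TRUE), -0.4)
})

test_that("GRAVY is bounded by the scale extremes on random sequences", {
  set.seed(11)
  for (rep in 1:50) {
    g <- compute_gravy(random_protein(sample(1:200, 1)))
    expect_gte(g, -4.5)
    expect_lte(g, 4.5)
  }
})

test_that("molecular weight is additive and hand-checkable", {
  # Gly-Gly: two average Gly residue masses plus one water
  expect_equal(compute_mw("GG"), (2 * 57.0519 + 18.01524) / 1000)
  set.seed(3)
  a <- random_protein(30)
  b <- random_protein(17)
  expect_equal(compute_mw(paste0(a, b)),
               compute_mw(a) + compute_mw(b) - 18.01524 / 1000)
  # strictly increasing in length
  expect_gt(compute_mw(paste0(a, "G")), compute_mw(a))
})

test_that("isoelectric point matches an independent fine-grid charge scan", {
  # no ionizable side chains: pI bracketed by the termini pKa values
  pep <- "GAVLG"
  pi_val <- compute_pi(pep)
  expect_gt(pi_val, 3.55)
  expect_lt(pi_val, 7.59)
  expect_equal(pi_val, grid_scan_pi(pep), tolerance = 2e-3)
  set.seed(21)
  for (rep in 1:5) {
    s <- random_protein(40)
    expect_equal(compute_pi(s), grid_scan_pi(s), tolerance = 2e-3)
  }
})

test_that("TM segment prediction handles uniform and planted cases", {
  expect_error(predict_tm_segments(strrep("I", 40), window = 18), "odd")
  segs <- predict_tm_segments(strrep("I", 40))
  expect_equal(nrow(segs), 1L)
  expect_equal(c(segs$start, segs$end), c(1L, 40L))
  expect_equal(nrow(predict_tm_segments(strrep("D", 40))), 0L)
})

test_that("two planted hydrophobic blocks give exactly two segments", {
  for (seed in 1:100) {
    set.seed(seed)
    flank <- paste(sample(c("D", "E", "K", "N", "Q", "R"), 15,
                          replace = TRUE), collapse = "")
    mid <- paste(sample(c("D", "E", "K", "N", "Q", "R"), 30,
                        replace = TRUE), collapse = "")
    block <- strrep("I", 23)
    seq <- paste0(flank, block, mid, block, flank)
    segs <- predict_tm_segments(seq)
    expect_equal(nrow(segs), 2L, info = paste("seed", seed))
    # each segment fully covers its planted block (16..38 and 69..91)
    expect_lte(segs$start[1], 16L)
    expect_gte(segs$end[1], 38L)
    expect_lte(segs$start[2], 69L)
    expect_gte(segs$end[2], 91L)
    naive <- naive_tm_segments(seq)
    expect_equal(segs$start, naive$start, info = paste("seed", seed))
    expect_equal(segs$end, naive$end, info = paste("seed", seed))
  }
})

test_that("annotate_protein extracts the planted signature end to end", {
  gen <- generate_aqp_proteins(list(
    seed = 8L, insert_max = 6L,
    members = load_roster()[load_roster()$name == "PruavPIP2;1", ]))
  ann <- annotate_protein("PruavPIP2;1", gen$records$sequence[1])
  expect_equal(ann$template_subfamily, "PIP")
  expect_equal(ann$arR, "FHTR")
  expect_equal(ann$froger, "QSAFW")
  expect_equal(ann$subfamily_call$subfamily, "PIP")
  expect_equal(ann$npa$triplet[1:2], c("NPA", "NPA"))
  path <- withr::local_tempfile(fileext = ".json")
  export_annotations_json(ann, path)
  back <- jsonlite::read_json(path)
  expect_equal(back[[1]]$arR, "FHTR")
  expect_equal(back[[1]]$subfamily, "PIP")
})
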