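# Independent oracles used across the suite. Each one recomputes a quantity
# by direct enumeration or a textbook formula, sharing no code path with the
# implementation it checks.

chars_of <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Exhaustive global-alignment score: explores every monotone alignment path
# (diagonal / up / left) carrying the previous move so affine gaps cost
# open + extend on the first column of a run and extend afterwards.
enum_align_score <- function(a, b, mat, gap_open, gap_extend) {
  ca <- chars_of(a)
  cb <- chars_of(b)
  na_ <- length(ca)
  nb <- length(cb)
  rec <- function(i, j, prev) {
    if (i > na_ && j > nb) return(0)
    best <- -Inf
    if (i <= na_ && j <= nb) {
      best <- max(best, mat[ca[i], cb[j]] + rec(i + 1L, j + 1L, "d"))
    }
    if (i <= na_) {
      cost <- gap_extend + if (identical(prev, "u")) 0 else gap_open
      best <- max(best, rec(i + 1L, j, "u") - cost)
    }
    if (j <= nb) {
      cost <- gap_extend + if (identical(prev, "l")) 0 else gap_open
      best <- max(best, rec(i, j + 1L, "l") - cost)
    }
    best
  }
  rec(1L, 1L, "start")
}

# --- Nei-Gojobori oracle -----------------------------------------------
# Textbook recomputation: translation through Biostrings::GENETIC_CODE,
# site fractions by explicit substitution enumeration, difference counts by
# explicit pathway enumeration with stop-intermediate exclusion, and the
# Jukes-Cantor transform applied to both proportions.

oracle_translate <- function(codon) {
  unname(Biostrings::GENETIC_CODE[[codon]])
}

oracle_codon_split <- function(cds) {
  n <- nchar(cds)
  substring(cds, seq(1, n, 3), seq(3, n, 3))
}

oracle_syn_sites <- function(codon) {
  bases <- c("A", "C", "G", "T")
  cc <- chars_of(codon)
  aa <- oracle_translate(codon)
  syn <- 0
  for (p in 1:3) {
    for (nb in bases[bases != cc[p]]) {
      mutant <- cc
      mutant[p] <- nb
      maa <- oracle_translate(paste(mutant, collapse = ""))
      if (maa == aa && maa != "*") syn <- syn + 1
    }
  }
  syn / 3
}

oracle_orderings <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (k in seq_along(v)) {
    for (tail in oracle_orderings(v[-k])) {
      out[[length(out) + 1L]] <- c(v[k], tail)
    }
  }
  out
}

oracle_path_counts <- function(c1, c2) {
  x <- chars_of(c1)
  y <- chars_of(c2)
  pos <- which(x != y)
  if (!length(pos)) return(c(0, 0))
  walk <- function(order, skip_stop) {
    cur <- x
    sd <- nd <- 0
    for (p in order) {
      nxt <- cur
      nxt[p] <- y[p]
      a1 <- oracle_translate(paste(cur, collapse = ""))
      a2 <- oracle_translate(paste(nxt, collapse = ""))
      if (skip_stop && a2 == "*") return(NULL)
      if (a1 == a2) sd <- sd + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(sd, nd)
  }
  paths <- lapply(oracle_orderings(pos), walk, skip_stop = TRUE)
  paths <- paths[!vapply(paths, is.null, logical(1))]
  if (!length(paths)) {
    paths <- lapply(oracle_orderings(pos), walk, skip_stop = FALSE)
  }
  Reduce(`+`, paths) / length(paths)
}

oracle_ng86 <- function(cds_a, cds_b) {
  ca <- oracle_codon_split(cds_a)
  cb <- oracle_codon_split(cds_b)
  S <- sum(mapply(function(p, q) {
    (oracle_syn_sites(p) + oracle_syn_sites(q)) / 2
  }, ca, cb))
  N <- 3 * length(ca) - S
  counts <- Reduce(`+`, mapply(oracle_path_counts, ca, cb, SIMPLIFY = FALSE))
  ps <- counts[1] / S
  pn <- counts[2] / N
  jc <- function(p) -0.75 * log(1 - 4 * p / 3)
  list(ka = jc(pn), ks = jc(ps), s_sites = S, n_sites = N)
}

# --- naive average-linkage oracle --------------------------------------
# O(n^3) agglomeration on a full distance matrix; inter-cluster distance is
# the arithmetic mean of all original pairwise distances between members.
naive_average_linkage_heights <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_along(clusters)[-length(clusters)]) {
      for (j in (i + 1L):length(clusters)) {
        dij <- mean(d[clusters[[i]], clusters[[j]]])
        if (dij < best_d) {
          best_d <- dij
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, best_d)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
  }
  heights
}

# --- fine-grid isoelectric-point oracle --------------------------------
# Locates the zero crossing of the Bjellqvist net-charge curve on a dense
# pH grid (no bisection involved).
grid_scan_pi <- function(seq, step = 1e-4) {
  const <- yaml::read_yaml(aqpscan_extdata("physchem_constants.yaml"))
  pka <- const$pka
  cc <- chars_of(seq)
  charge_at <- function(pH) {
    first <- cc[1]
    last <- cc[length(cc)]
    ntp <- if (!is.null(pka$nterm[[first]])) pka$nterm[[first]] else pka$nterm$default
    ctp <- if (!is.null(pka$cterm[[last]])) pka$cterm[[last]] else pka$cterm$default
    pos <- 1 / (1 + 10^(pH - ntp)) +
      sum(cc == "H") / (1 + 10^(pH - pka$side_chain$H)) +
      sum(cc == "K") / (1 + 10^(pH - pka$side_chain$K)) +
      sum(cc == "R") / (1 + 10^(pH - pka$side_chain$R))
    neg <- 1 / (1 + 10^(ctp - pH)) +
      sum(cc == "D") / (1 + 10^(pka$side_chain$D - pH)) +
      sum(cc == "E") / (1 + 10^(pka$side_chain$E - pH)) +
      sum(cc == "C") / (1 + 10^(pka$side_chain$C - pH)) +
      sum(cc == "Y") / (1 + 10^(pka$side_chain$Y - pH))
    pos - neg
  }
  grid <- seq(0, 14, by = step)
  charges <- vapply(grid, charge_at, numeric(1))
  grid[which.min(abs(charges))]
}

# Naive sliding-window transmembrane segments: per-center window means
# computed directly with mean(), hot centers expanded to full windows and
# merged by interval arithmetic.
naive_tm_segments <- function(seq, window = 19L, threshold = 1.6) {
  const <- yaml::read_yaml(aqpscan_extdata("physchem_constants.yaml"))
  kd <- unlist(const$kyte_doolittle)[chars_of(seq)]
  half <- (window - 1L) / 2
  centers <- (half + 1L):(length(kd) - half)
  hot <- centers[vapply(centers, function(c) {
    mean(kd[(c - half):(c + half)]) >= threshold
  }, logical(1))]
  if (!length(hot)) return(data.frame(start = integer(), end = integer()))
  ivs <- data.frame(start = hot - half, end = hot + half)
  merged <- ivs[1, ]
  for (i in seq_len(nrow(ivs))[-1]) {
    last <- nrow(merged)
    if (ivs$start[i] <= merged$end[last] + 1L) {
      merged$end[last] <- max(merged$end[last], ivs$end[i])
    } else {
      merged <- rbind(merged, ivs[i, ])
    }
  }
  merged
}

# Random protein sequence over the canonical alphabet.
random_protein <- function(n) {
  paste(sample(c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
               n, replace = TRUE), collapse = "")
}

# Random stop-free CDS of n codons.
random_sense_cds <- function(n) {
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  paste(sample(sense, n, replace = TRUE), collapse = "")
}
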