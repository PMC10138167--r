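test_that("pfaffl_ratio obeys its closed-form contracts", {
  expect_equal(pfaffl_ratio(2, 0, 2, 0), 1.0)
  expect_equal(pfaffl_ratio(2, 1, 2, 0), 2.0)
  expect_error(pfaffl_ratio(2, Inf, 2, 0), "non-finite")
  expect_error(pfaffl_ratio(2.5, 1, 2, 0), "efficiencies")
  # with equal efficiencies the ratio collapses to E^(dct_t - dct_r),
  # i.e. the classic ddCt formula at E = 2
  set.seed(63)
  for (rep in 1:100) {
    e <- runif(1, 1.6, 2)
    dt <- runif(1, -5, 5)
    dr <- runif(1, -5, 5)
    expect_equal(pfaffl_ratio(e, dt, e, dr), e^(dt - dr))
  }
  expect_equal(pfaffl_ratio(2, 3.2, 2, 1.1), 2^(3.2 - 1.1))
})

test_that("a table where every sample equals the calibrator gives zeros", {
  gen <- generate_ct_table(list(
    seed = 1L, noise_sd = 0,
    log2fc = matrix(0, 6, 3,
                    dimnames = list(sprintf("synthAQP%d", 1:6),
                                    c("control", "s1", "s2")))))
  em <- build_matrix(gen$ct, gen$reference_gene, gen$calibrator)
  expect_true(all(em$log2 == 0))
})

test_that("noise-free planted fold-changes are recovered to machine precision", {
  gen <- generate_ct_table(list(seed = 92L, noise_sd = 0))
  em <- build_matrix(gen$ct, gen$reference_gene, gen$calibrator)
  expect_equal(em$log2, gen$truth[rownames(em$log2), colnames(em$log2)],
               tolerance = 1e-12)
  expect_true(all(em$log2[, em$calibrator] == 0))
})

test_that("noisy recovery lands within 3 standard errors for >= 95% of cells", {
  sd_ct <- 0.2
  n_bio <- 3L
  n_tech <- 2L
  hits <- 0L
  total <- 0L
  for (seed in 1:200) {
    gen <- generate_ct_table(list(seed = seed, noise_sd = sd_ct,
                                  n_bio = n_bio, n_tech = n_tech))
    em <- build_matrix(gen$ct, gen$reference_gene, gen$calibrator)
    truth <- gen$truth[rownames(em$log2), colnames(em$log2)]
    # each log2 cell is a difference of 4 replicate-mean Ct values
    # (gene/ref x sample/calibrator), each mean over n_bio*n_tech draws
    se <- sqrt(4 * sd_ct^2 / (n_bio * n_tech))
    off <- colnames(truth) != em$calibrator
    dev <- abs(em$log2[, off] - truth[, off])
    hits <- hits + sum(dev <= 3 * se)
    total <- total + length(dev)
  }
  expect_gte(hits / total, 0.95)
})

test_that("bias shrinks as biological replication grows", {
  mean_abs_dev <- vapply(c(3L, 10L, 30L), function(n_bio) {
    devs <- vapply(1:30, function(seed) {
      gen <- generate_ct_table(list(seed = seed, noise_sd = 0.4,
                                    n_bio = n_bio, n_tech = 1L))
      em <- build_matrix(gen$ct, gen$reference_gene, gen$calibrator)
      truth <- gen$truth[rownames(em$log2), colnames(em$log2)]
      off <- colnames(truth) != em$calibrator
      mean(abs(em$log2[, off] - truth[, off]))
    }, numeric(1))
    mean(devs)
  }, numeric(1))
  expect_lt(mean_abs_dev[3], mean_abs_dev[1])
})

test_that("matrix building is invariant to replicate and sample order", {
  gen <- generate_ct_table(list(seed = 55L))
  em <- build_matrix(gen$ct, gen$reference_gene, gen$calibrator)
  shuffled <- gen$ct[sample(nrow(gen$ct)), ]
  em2 <- build_matrix(shuffled, gen$reference_gene, gen$calibrator)
  expect_equal(em$log2[rownames(em$log2), colnames(em$log2)],
               em2$log2[rownames(em$log2), colnames(em$log2)])
})

test_that("not-detected cells are masked, never imputed", {
  gen <- generate_ct_table(list(seed = 13L, noise_sd = 0))
  ct <- gen$ct
  g <- rownames(gen$truth)[1]
  ct$ct[ct$gene == g & ct$sample == "s1"] <- NA
  em <- build_matrix(ct, gen$reference_gene, gen$calibrator)
  expect_true(em$mask[g, "s1"])
  expect_true(is.na(em$log2[g, "s1"]))
  expect_false(any(em$mask[g, c("control", "s2")]))
  # gene missing in the calibrator: whole row masked, with a warning
  ct2 <- gen$ct
  ct2$ct[ct2$gene == g & ct2$sample == gen$calibrator] <- NA
  expect_warning(em2 <- build_matrix(ct2, gen$reference_gene,
                                     gen$calibrator),
                 "calibrator")
  expect_true(all(em2$mask[g, ]))
})

test_that("regulation calls respect thresholds, boundaries and masks", {
  m <- matrix(c(0, 1, -1, 2.5, -0.4, NA), 2, 3,
              dimnames = list(c("g1", "g2"), c("a", "b", "c")))
  calls <- call_regulation(m, threshold = 1)
  expect_equal(calls["g1", "a"], "nc")
  expect_equal(calls["g2", "a"], "up")     # exactly at threshold: closed
  expect_equal(calls["g1", "b"], "down")
  expect_equal(calls["g2", "b"], "up")
  expect_equal(calls["g1", "c"], "nc")
  expect_equal(calls["g2", "c"], "nd")
  expect_error(call_regulation(m, threshold = 0), "> 0")
})

test_that("planted regulation calls at |log2FC| = 2 are recovered exactly", {
  fc <- matrix(c(0, 0, 0, 2, -2, 0, 0, 2, -2), 3, 3,
               dimnames = list(sprintf("synthAQP%d", 1:3),
                               c("control", "s1", "s2")))
  gen <- generate_ct_table(list(seed = 70L, noise_sd = 0,
                                genes = rownames(fc), log2fc = fc))
  em <- build_matrix(gen$ct, gen$reference_gene, gen$calibrator)
  calls <- call_regulation(em, threshold = 1)
  expected <- ifelse(fc >= 1, "up", ifelse(fc <= -1, "down", "nc"))
  expect_equal(calls[rownames(fc), colnames(fc)], expected)
})

test_that("up/down counts are monotone non-increasing in the threshold", {
  gen <- generate_ct_table(list(seed = 44L))
  em <- build_matrix(gen$ct, gen$reference_gene, gen$calibrator)
  thresholds <- c(0.5, 1, 2, 3)
  counts <- vapply(thresholds, function(th) {
    calls <- call_regulation(em, th)
    c(sum(calls == "up"), sum(calls == "down"))
  }, numeric(2))
  expect_true(all(diff(counts[1, ]) <= 0))
  expect_true(all(diff(counts[2, ]) <= 0))
})

test_that("clustering merges identical profiles first and orders leaves", {
  m <- rbind(a = c(0, 0, 0), b = c(0, 0, 0), c = c(5, 5, 5))
  cl <- hierarchical_cluster(m)
  expect_equal(cl$hclust$height[1], 0)
  expect_setequal(cl$leaf_order, c("a", "b", "c"))
  # forced topology: the close pair merges first
  d3 <- rbind(x = c(0, 10), y = c(1, 10), z = c(10, 0))
  cl3 <- hierarchical_cluster(d3)
  first <- cl3$hclust$merge[1, ]
  expect_setequal(cl3$hclust$labels[-first], c("x", "y"))
})

test_that("merge heights equal the naive O(n^3) agglomeration oracle", {
  set.seed(808)
  m <- matrix(rnorm(20 * 6), 20, 6,
              dimnames = list(sprintf("p%02d", 1:20), NULL))
  cl <- hierarchical_cluster(m)
  d <- pairwise_complete_dist(m)
  expect_equal(sort(cl$hclust$height),
               sort(naive_average_linkage_heights(d)),
               tolerance = 1e-10)
})

test_that("profiles with too few shared cells are excluded with a warning", {
  m <- rbind(a = c(1, 2, 3, 4), b = c(1.1, 2, 3, 4.2),
             c = c(NA, NA, NA, 5), d = c(0, 1, 2, 3))
  expect_warning(cl <- hierarchical_cluster(m), "excluding")
  expect_setequal(cl$leaf_order, c("a", "b", "d"))
})
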