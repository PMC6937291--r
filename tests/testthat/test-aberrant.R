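test_that("normally unmethylated CGI reference keeps only fully quiet islands", {
  bbeta <- make_bbeta(list(b1 = c(0.05, 0.10), b2 = c(0.05, 0.35),
                           b3 = c(0.50, 0.60), b4 = c(0.01, 0.01)),
                      c("N1", "N2"))
  blocks <- data.frame(
    block_id = c("b1", "b2", "b3", "b4"),
    cgi_relation = c("Island", "Island", "Island", "OpenSea"),
    stringsAsFactors = FALSE)
  out <- normally_unmethylated_cgi_blocks(bbeta, blocks, c("N1", "N2"))
  expect_equal(out, "b1")  # b2/b3 methylated in a normal, b4 not an island
  expect_error(normally_unmethylated_cgi_blocks(bbeta, blocks, character(0)),
               "normal")
})

test_that("the reference set recovers the planted quiet-island blocks", {
  cfg <- sim_config(seed = 2, noise = FALSE)
  sim <- simulate_beta_cohort(cfg)
  bb <- block_beta(sim$beta, sim$blocks)
  out <- normally_unmethylated_cgi_blocks(bb, sim$blocks, sim$truth$normals)
  expect_equal(out, sim$truth$reference_blocks)
})

test_that("aberrant blocks need quiet normals and enough methylated tumors", {
  samples <- c(paste0("N", 1:3), paste0("T", 1:28))
  tumors <- paste0("T", 1:28)
  b1 <- c(0.05, 0.08, 0.10, rep(0.6, 7), rep(0.1, 21))
  bbeta <- make_bbeta(list(b1 = b1), samples)
  out <- call_aberrant_blocks(bbeta, tumors, paste0("N", 1:3),
                              aberrant_config(min_tumor_count = 6))
  expect_equal(out$block_id, "b1")
  expect_equal(out$n_methylated_tumors, 7L)
  out8 <- call_aberrant_blocks(bbeta, tumors, paste0("N", 1:3),
                               aberrant_config(min_tumor_count = 8))
  expect_equal(nrow(out8), 0)
  expect_error(call_aberrant_blocks(bbeta, character(0), paste0("N", 1:3)),
               "tumor")
  expect_error(call_aberrant_blocks(bbeta, tumors, tumors[1]), "disjoint")
})

test_that("noise-free planted cohort is recovered exactly", {
  cfg <- sim_config(seed = 3, noise = FALSE, n_high_methylators = 0)
  sim <- simulate_beta_cohort(cfg)
  bb <- block_beta(sim$beta, sim$blocks)
  calls <- call_aberrant_blocks(bb, sim$truth$tumors, sim$truth$normals)
  expect_setequal(calls$block_id, sim$truth$aberrant_blocks)
  expect_equal(length(sim$truth$aberrant_blocks), 40)
  # reported counts equal the planted carrier-set sizes
  expect_equal(calls$n_methylated_tumors,
               unname(sim$truth$carrier_counts[calls$block_id]))
})

test_that("aberrant calling is monotone in its thresholds", {
  sim <- simulate_beta_cohort(sim_config(seed = 7))
  bb <- block_beta(sim$beta, sim$blocks)
  tu <- sim$truth$tumors
  no <- sim$truth$normals
  base <- call_aberrant_blocks(bb, tu, no, aberrant_config())
  stricter <- call_aberrant_blocks(bb, tu, no,
                                   aberrant_config(min_tumor_count = 10))
  expect_true(all(stricter$block_id %in% base$block_id))
  looser <- call_aberrant_blocks(bb, tu, no,
                                 aberrant_config(meth_threshold = 0.3))
  expect_true(all(base$block_id %in% looser$block_id))
})

test_that("variable-block selection ranks by variance with stable ties", {
  bbeta <- make_bbeta(list(
    a = c(0.5, 0.5, 0.5), b = c(0.4, 0.5, 0.6),
    c = c(0.2, 0.5, 0.8), d = c(0.35, 0.5, 0.65)),
    c("S1", "S2", "S3"))
  expect_equal(select_variable_blocks(bbeta, n = 2), c("c", "d"))
  expect_equal(sort(select_variable_blocks(bbeta, n = 4)),
               c("a", "b", "c", "d"))
  expect_error(select_variable_blocks(bbeta, n = 5), "exceeds")
})

test_that("variable-block selection matches an exhaustive sort oracle", {
  bbeta <- withr::with_seed(21, random_beta(5000, 30))
  got <- select_variable_blocks(bbeta, n = 500)
  v <- apply(bbeta, 1, stats::var)
  oracle <- rownames(bbeta)[order(-v, rownames(bbeta))][1:500]
  expect_equal(got, oracle)
  # invariant to sample column order
  shuffled <- bbeta[, withr::with_seed(22, sample(ncol(bbeta)))]
  expect_equal(select_variable_blocks(shuffled, n = 500), got)
})

test_that("two samples merge at their Euclidean distance", {
  bbeta <- make_bbeta(list(a = c(0.1, 0.5), b = c(0.2, 0.9)),
                      c("S1", "S2"))
  cl <- cluster_samples(bbeta, k = 2)
  expect_equal(cl$hclust$height,
               sqrt((0.1 - 0.5)^2 + (0.2 - 0.9)^2))
  expect_error(cluster_samples(bbeta, samples = "S1"), "2 samples")
})

test_that("clustering recovers the planted high-methylator subgroup", {
  skip_if_not_installed("mclust")
  sim <- simulate_beta_cohort(sim_config(seed = 4))
  bb <- block_beta(sim$beta, sim$blocks)
  vb <- select_variable_blocks(bb, sim$truth$tumors, n = 500)
  cl <- cluster_samples(bb, vb, sim$truth$tumors, seed = 4, k = 2)
  truth_labels <- as.integer(names(cl$labels_at_k) %in%
                               sim$truth$high_samples)
  expect_equal(mclust::adjustedRandIndex(cl$labels_at_k, truth_labels), 1.0)
})

test_that("clustering is invariant to sample order and drops NA blocks", {
  sim <- simulate_beta_cohort(sim_config(seed = 4, n_genes = 200))
  bb <- block_beta(sim$beta, sim$blocks)
  tu <- sim$truth$tumors
  cl1 <- cluster_samples(bb, samples = tu, seed = 1)
  cl2 <- cluster_samples(bb, samples = rev(tu), seed = 1)
  expect_identical(cl1$hclust$merge, cl2$hclust$merge)
  expect_identical(cl1$hclust$height, cl2$hclust$height)
  expect_identical(cl1$labels_at_k, cl2$labels_at_k)

  bb_na <- bb
  bb_na[1, tu[1]] <- NA
  expect_warning(cl3 <- cluster_samples(bb_na, samples = tu, seed = 1),
                 "missing")
  expect_false(rownames(bb)[1] %in% cl3$blocks_used)
})

test_that("the element cap triggers a seeded subsample", {
  bbeta <- withr::with_seed(30, random_beta(300, 6))
  cl_a <- cluster_samples(bbeta, element_cap = 100, seed = 5)
  cl_b <- cluster_samples(bbeta, element_cap = 100, seed = 5)
  expect_equal(length(cl_a$blocks_used), 100)
  expect_identical(cl_a$blocks_used, cl_b$blocks_used)
  cl_c <- cluster_samples(bbeta, element_cap = 100, seed = 6)
  expect_false(identical(cl_a$blocks_used, cl_c$blocks_used))
})

test_that("methylated fraction counts methylated reference blocks", {
  vals <- c(rep(0.5, 3), rep(0.05, 7))
  bbeta <- matrix(vals, ncol = 1,
                  dimnames = list(sprintf("b%02d", 1:10), "S1"))
  refs <- rownames(bbeta)
  expect_equal(methylated_fraction(bbeta, "S1", refs, "tissue"), 0.3)
  # permutation invariance
  expect_equal(methylated_fraction(bbeta, "S1", rev(refs), "tissue"), 0.3)
  # zero case
  expect_equal(
    methylated_fraction(bbeta, "S1", refs[4:10], "tissue"), 0)
  # all missing -> error
  bbeta[, 1] <- NA
  expect_error(methylated_fraction(bbeta, "S1", refs), "missing")
  expect_error(methylated_fraction(bbeta, "S1", character(0)), "nonempty")
})

test_that("a planted high-methylator has the planted methylation rate", {
  sim <- simulate_beta_cohort(sim_config(seed = 5))
  bb <- block_beta(sim$beta, sim$blocks)
  refs <- sim$truth$reference_blocks
  f <- methylated_fraction(bb, sim$truth$high_samples[1], refs, "tissue")
  ci <- 1.96 * sqrt(0.2 * 0.8 / length(refs))
  expect_true(abs(f - 0.20) <= ci)
})
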