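test_that("normalization scales each sample's 75th percentile to 1", {
  m <- cbind(S1 = c(1, 2, 3, 4), S2 = c(5, 5, 5, 5))
  rownames(m) <- paste0("p", 1:4)
  norm <- normalize_75th(m)
  expect_equal(norm[, "S1"], c(1, 2, 3, 4) / 3.25,
               ignore_attr = TRUE)
  expect_equal(unname(norm[, "S2"]), rep(1, 4))
  expect_true(attr(norm, "normalized"))
})

test_that("normalization is idempotent and its post-condition holds", {
  m <- withr::with_seed(40, matrix(stats::rexp(1000 * 4, 1), 1000, 4,
                                   dimnames = list(paste0("p", 1:1000),
                                                   paste0("S", 1:4))))
  norm <- normalize_75th(m)
  q <- apply(norm, 2, stats::quantile, probs = 0.75, names = FALSE)
  expect_equal(unname(q), rep(1, 4), tolerance = 1e-9)
  expect_equal(normalize_75th(norm), norm)
})

test_that("degenerate columns are rejected", {
  m <- cbind(S1 = c(0, 0, 0, 0, 5))
  rownames(m) <- paste0("p", 1:5)
  expect_error(normalize_75th(m), "75th percentile")
  expect_error(normalize_75th(cbind(S1 = c(-1, 2))), "nonnegative")
})

test_that("gene aggregation averages member probes", {
  m <- matrix(c(0.8, 1.2, 0.7), ncol = 1,
              dimnames = list(c("p1", "p2", "p3"), "S1"))
  map <- data.frame(probe_id = c("p1", "p2", "p3"),
                    gene = c("A", "A", "B"))
  g <- aggregate_genes(m, map)
  expect_equal(g["A", "S1"], 1.0)
  expect_equal(g["B", "S1"], 0.7)
  expect_error(aggregate_genes(m, map[0, ]), "empty")
})

test_that("gene aggregation matches a per-gene loop oracle", {
  m <- withr::with_seed(41, matrix(stats::rexp(200 * 5), 200, 5,
                                   dimnames = list(paste0("p", 1:200),
                                                   paste0("S", 1:5))))
  map <- data.frame(probe_id = paste0("p", 1:200),
                    gene = paste0("G", withr::with_seed(
                      42, sample(60, 200, replace = TRUE))))
  g <- aggregate_genes(m, map)
  for (gene in sample(rownames(g), 10)) {
    pids <- map$probe_id[map$gene == gene]
    expect_equal(g[gene, ], colMeans(m[pids, , drop = FALSE]))
  }
})

test_that("baseline expression requires every group above threshold", {
  m <- matrix(c(1.5, 1.5, 2.0, 0.1), nrow = 2,
              dimnames = list(c("A", "B"), c("MSC1", "OB1")))
  groups <- list(msc = "MSC1", ob = "OB1")
  expect_equal(expressed_in_baseline(m, groups, 0.5), "A")
  expect_error(expressed_in_baseline(m, list(msc = character(0)), 0.5),
               "empty")
})

test_that("planted baseline-expressed genes are recovered noise-free", {
  cfg <- sim_config(seed = 6, noise = FALSE, n_genes = 500)
  sim <- simulate_beta_cohort(cfg)
  ex <- simulate_expression(cfg, sim$truth)
  ge <- aggregate_genes(normalize_75th(ex$expr), ex$probe_gene)
  got <- expressed_in_baseline(ge, ex$baseline_groups, 0.5)
  expect_equal(got, ex$expressed_genes)
})

test_that("induction screen computes floored log2 ratios", {
  m <- matrix(c(0.5, 1.0, 0.001, 1.2, 1.0, 0.001), ncol = 2,
              dimnames = list(c("A", "B", "C"), c("mock", "aza")))
  out <- induction_screen(m, "mock", "aza", log2_threshold = 1,
                          floor = 0.01)
  expect_equal(out$log2_ratio[out$gene == "A"], log2(1.2 / 0.5))
  expect_true(out$induced[out$gene == "A"])
  expect_equal(out$log2_ratio[out$gene == "B"], 0)
  expect_false(out$induced[out$gene == "B"])
  # both below floor: ratio 0, not induced
  expect_equal(out$log2_ratio[out$gene == "C"], 0)
  expect_error(induction_screen(m, "mock", "nope"), "absent")
})

test_that("induction screen is monotone in its threshold", {
  cfg <- sim_config(seed = 7, n_genes = 500)
  sim <- simulate_beta_cohort(cfg)
  ex <- simulate_expression(cfg, sim$truth)
  ge <- aggregate_genes(normalize_75th(ex$expr), ex$probe_gene)
  lo <- induction_screen(ge, "CL1_mock", "CL1_aza", log2_threshold = 1)
  hi <- induction_screen(ge, "CL1_mock", "CL1_aza", log2_threshold = 1.5)
  expect_true(all(lo$gene[hi$induced] %in% lo$gene[lo$induced]))
})

test_that("planted induced genes are detected at the default threshold", {
  cfg <- sim_config(seed = 7, n_genes = 500)
  sim <- simulate_beta_cohort(cfg)
  ex <- simulate_expression(cfg, sim$truth)
  ge <- aggregate_genes(normalize_75th(ex$expr), ex$probe_gene)
  out <- induction_screen(ge, "CL1_mock", "CL1_aza")
  planted <- sim$truth$silenced_genes$CL1
  recall <- mean(planted %in% out$gene[out$induced])
  expect_gte(recall, 0.95)
})

test_that("a unit fold-change plants no induced genes (noise-free null)", {
  cfg <- sim_config(seed = 8, noise = FALSE, induction_true_fold = 1,
                    n_genes = 300)
  sim <- simulate_beta_cohort(cfg)
  ex <- simulate_expression(cfg, sim$truth)
  ge <- aggregate_genes(normalize_75th(ex$expr), ex$probe_gene)
  out <- induction_screen(ge, "CL1_mock", "CL1_aza")
  expect_false(any(out$induced))
})

test_that("aggregation then screening is invariant to probe order", {
  cfg <- sim_config(seed = 9, n_genes = 200)
  sim <- simulate_beta_cohort(cfg)
  ex <- simulate_expression(cfg, sim$truth)
  norm <- normalize_75th(ex$expr)
  perm <- withr::with_seed(43, sample(nrow(norm)))
  g1 <- aggregate_genes(norm, ex$probe_gene)
  g2 <- aggregate_genes(norm[perm, ], ex$probe_gene)
  expect_equal(induction_screen(g1, "CL1_mock", "CL1_aza"),
               induction_screen(g2, "CL1_mock", "CL1_aza"))
})
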