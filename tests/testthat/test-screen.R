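# A hand-built five-gene cohort exercising each universe condition:
#   G1: all conditions met; G2: methylated block is gene-Body only;
#   G3: not expressed in baseline; G4: too few methylated tumors;
#   G5: satisfies methylation but absent from the expression platform.
toy_universe_inputs <- function() {
  probes <- rbind(
    make_probes(paste0("cg", 1:2), gene = "G1", cgi_id = "c1",
                pos = 1:2),
    make_probes("cg3", gene = "G2", tss_relation = "Body",
                cgi_relation = "OpenSea", cgi_id = NA, pos = 3),
    make_probes("cg4", gene = "G3", cgi_id = "c3", pos = 4),
    make_probes("cg5", gene = "G4", cgi_id = "c4", pos = 5),
    make_probes("cg6", gene = "G5", cgi_id = "c5", pos = 6))
  blocks <- assemble_blocks(probes)
  samples <- c("N1", "N2", paste0("T", 1:10))
  meth_in <- function(n_tumors) c(0.05, 0.05, rep(0.8, n_tumors),
                                  rep(0.05, 10 - n_tumors))
  beta <- rbind(cg1 = meth_in(8), cg2 = meth_in(8), cg3 = meth_in(9),
                cg4 = meth_in(7), cg5 = meth_in(2), cg6 = meth_in(8))
  colnames(beta) <- samples
  bbeta <- block_beta(beta, blocks)
  list(blocks = blocks, bbeta = bbeta, tumors = paste0("T", 1:10),
       normals = c("N1", "N2"),
       baseline = c("G1", "G2", "G4", "G5"),
       evaluable = c("G1", "G2", "G3", "G4"))
}

test_that("the eligible universe applies each condition (brute force)", {
  x <- toy_universe_inputs()
  crit <- screen_criteria(aberrant_config(min_tumor_count = 6))
  uni <- eligible_gene_universe(x$blocks, x$bbeta, x$tumors, x$normals,
                                x$baseline, x$evaluable, crit)
  # brute-force check of each gene against the three conditions
  expect_equal(uni$gene, "G1")
  expect_equal(uni$n_methylated_tumors, 8L)
  expect_error(eligible_gene_universe(x$blocks, x$bbeta, x$tumors,
                                      x$normals, character(0), x$evaluable),
               "empty")
})

test_that("universe recovers planted aberrant-expressed genes on a cohort", {
  cfg <- sim_config(seed = 8, noise = FALSE)
  sim <- simulate_beta_cohort(cfg)
  ex <- simulate_expression(cfg, sim$truth)
  bb <- block_beta(sim$beta, sim$blocks)
  ge <- aggregate_genes(normalize_75th(ex$expr), ex$probe_gene)
  base <- expressed_in_baseline(ge, ex$baseline_groups)
  uni <- eligible_gene_universe(sim$blocks, bb, sim$truth$tumors,
                                sim$truth$normals, base, rownames(ge))
  implied <- true_aberrant_blocks(sim$truth)
  expected <- intersect(
    names(sim$truth$gene_block)[sim$truth$gene_block %in% implied],
    ex$expressed_genes)
  expect_setequal(uni$gene, expected)
})

test_that("screen candidates require methylation and induction jointly", {
  uni <- structure(data.frame(gene = c("GA", "GB"),
                              block_id = c("bA", "bB"),
                              n_methylated_tumors = c(8L, 8L),
                              stringsAsFactors = FALSE),
                   class = c("gene_universe", "data.frame"))
  clb <- make_bbeta(list(bA = 0.9, bB = 0.5), "CL_mock")
  induction <- data.frame(gene = c("GA", "GB"), log2_ratio = c(1.5, 1.5),
                          induced = TRUE)
  out <- run_screen(uni, clb, "CL_mock", induction)
  expect_true(out$passes[out$gene == "GA"])
  # beta 0.5 is partial under the cell-line scheme, not methylated
  expect_false(out$passes[out$gene == "GB"])
  # dropping the cell-line requirement turns it into a pure induction screen
  out2 <- run_screen(uni, clb, "CL_mock", induction,
                     screen_criteria(require_cell_line_methylated = FALSE))
  expect_true(all(out2$passes))
  expect_error(run_screen(uni, clb, "nope", induction), "absent")
})

test_that("end-to-end screen recovers planted silenced genes", {
  cfg <- sim_config(seed = 8, aberrant_block_fraction = 0.05,
                    n_silenced = 50)
  sim <- simulate_beta_cohort(cfg)
  ex <- simulate_expression(cfg, sim$truth)
  bb <- block_beta(sim$beta, sim$blocks)
  ge <- aggregate_genes(normalize_75th(ex$expr), ex$probe_gene)
  base <- expressed_in_baseline(ge, ex$baseline_groups)
  crit <- screen_criteria()
  uni <- eligible_gene_universe(sim$blocks, bb, sim$truth$tumors,
                                sim$truth$normals, base, rownames(ge), crit)
  ind <- induction_screen(ge, "CL1_mock", "CL1_aza")
  out <- run_screen(uni, bb, "CL1_mock", ind, crit)
  cand <- out$gene[out$passes]
  planted <- sim$truth$silenced_genes$CL1
  expect_gte(mean(planted %in% cand), 0.95)
  expect_lte(mean(!(cand %in% planted)), 0.02)
  # candidates are a subset of the universe, sorted by induction
  expect_true(all(cand %in% uni$gene))
  expect_true(!is.unsorted(rev(out$log2_induction)))
})

test_that("tightening any single criterion never adds candidates", {
  cfg <- sim_config(seed = 10, aberrant_block_fraction = 0.05,
                    n_silenced = 50)
  sim <- simulate_beta_cohort(cfg)
  ex <- simulate_expression(cfg, sim$truth)
  bb <- block_beta(sim$beta, sim$blocks)
  ge <- aggregate_genes(normalize_75th(ex$expr), ex$probe_gene)
  base <- expressed_in_baseline(ge, ex$baseline_groups)
  uni <- eligible_gene_universe(sim$blocks, bb, sim$truth$tumors,
                                sim$truth$normals, base, rownames(ge))
  ind <- induction_screen(ge, "CL1_mock", "CL1_aza")
  cand <- function(crit) {
    out <- run_screen(uni, bb, "CL1_mock", ind, crit)
    out$gene[out$passes]
  }
  base_cand <- cand(screen_criteria())
  expect_true(all(cand(screen_criteria(induction_log2_threshold = 2))
                  %in% base_cand))
  expect_true(all(cand(screen_criteria(cell_line_meth_threshold = 0.9))
                  %in% base_cand))
  # an unattainable induction threshold empties the list
  expect_length(cand(screen_criteria(induction_log2_threshold = Inf)), 0)
})

test_that("demethylation deltas are reported in percentage points", {
  uni <- data.frame(gene = c("GA", "GB"), block_id = c("bA", "bB"))
  bbeta <- make_bbeta(list(bA = c(0.80, 0.35), bB = c(0.6, 0.6)),
                      c("mock", "aza"))
  out <- demethylation_delta(bbeta, "mock", "aza", uni)
  expect_equal(out$delta_pp[out$gene == "GA"], 45)
  expect_equal(out$delta_pp[out$gene == "GB"], 0)
  expect_error(demethylation_delta(bbeta, "mock", "gone", uni), "absent")
})

test_that("planted demethylation effects fall in the planted interval", {
  cfg <- sim_config(seed = 8, noise = FALSE)
  sim <- simulate_beta_cohort(cfg)
  bb <- block_beta(sim$beta, sim$blocks)
  sil <- sim$truth$silenced_genes$CL1
  uni <- data.frame(gene = sil,
                    block_id = unname(sim$truth$gene_block[sil]))
  out <- demethylation_delta(bb, "CL1_mock", "CL1_aza", uni)
  expect_true(all(out$delta_pp >= 18 - 1e-9))
  expect_true(all(out$delta_pp <= 51 + 1e-9))
  expect_equal(out$delta_pp / 100,
               unname(sim$truth$demethylation_delta$CL1[out$gene]),
               tolerance = 1e-12)
})
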