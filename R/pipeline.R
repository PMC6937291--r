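#' Run the full methylation-analysis workflow
#'
#' Wires the analysis stages into one deterministic run: manifest loading
#' and block assembly, block-level beta summarization, the
#' normally-unmethylated CpG-island reference set, aberrant-block calls,
#' most-variable-block selection and hierarchical clustering, per-sample
#' methylated-CGI fractions, and — when expression inputs are configured —
#' the integrated methylation-silencing screen per cell line. qMSP tables
#' and primary-metastasis pairs are processed when configured. All result
#' tables are written to the output directory together with a run manifest
#' (configuration echo, package version); given identical inputs, seed and
#' configuration, result files are byte-identical across runs.
#'
#' @param config Either a path to a YAML file or a named list with
#'   elements: `manifest`, `beta`, `sample_sheet` (paths), `out_dir`,
#'   `seed`; optional `expression`, `probe_gene_map` (paths), `msc_samples`,
#'   `ob_samples` (sample-id vectors), `qmsp` (path); optional scalar
#'   overrides `meth_threshold`, `unmeth_threshold`, `min_tumor_count`,
#'   `baseline_threshold`, `induction_log2_threshold`,
#'   `cell_line_meth_threshold`, `n_variable_blocks`, `element_cap`,
#'   `linkage`, `k`, `shared_fraction_min`. Cell lines are paired from the
#'   sample sheet (`<id>_mock` / `<id>_aza` with groups `mock`/`treated`);
#'   primary-metastasis pairs come from rows sharing a `patient_id` with
#'   groups `tumor_primary` and `tumor_metastasis`.
#' @return Invisibly, a list of the in-memory stage results; side effect is
#'   the written output directory.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- pipeline_defaults(config)
  for (input in c("manifest", "beta", "sample_sheet")) {
    if (is.null(cfg[[input]])) stop("config is missing input: ", input)
    if (!file.exists(cfg[[input]])) {
      stop("input file not found (", input, "): ", cfg[[input]])
    }
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)

  probes <- load_manifest(cfg$manifest)
  beta <- read_beta_matrix(cfg$beta)
  sheet <- read_sample_sheet(cfg$sample_sheet)
  blocks <- assemble_blocks(probes)
  bbeta <- block_beta(beta, blocks)

  acfg <- aberrant_config(meth_threshold = cfg$meth_threshold,
                          unmeth_threshold = cfg$unmeth_threshold,
                          min_tumor_count = cfg$min_tumor_count)
  normals <- sheet$sample_id[sheet$group == "normal"]
  tumors <- sheet$sample_id[sheet$group == "tumor_primary"]

  block_table <- blocks[c("block_id", "gene", "tss_relation",
                          "cgi_relation", "cgi_id", "n_probes")]
  utils::write.table(block_table, file.path(cfg$out_dir, "blocks.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  write_value_matrix(bbeta, file.path(cfg$out_dir, "block_beta.tsv"),
                     id_col = "block_id")

  results <- list(blocks = blocks, block_beta = bbeta)

  if (length(normals) > 0 && length(tumors) > 0) {
    reference <- normally_unmethylated_cgi_blocks(bbeta, blocks, normals,
                                                  acfg)
    aberrant <- call_aberrant_blocks(bbeta, tumors, normals, acfg)
    aberrant <- merge(aberrant,
                      blocks[c("block_id", "gene")], by = "block_id")
    aberrant <- aberrant[order(aberrant$block_id),
                         c("block_id", "gene", "n_methylated_tumors",
                           "normal_max_beta")]
    utils::write.table(aberrant,
                       file.path(cfg$out_dir, "aberrant_blocks.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "")

    variable <- select_variable_blocks(
      bbeta, tumors, n = min(cfg$n_variable_blocks,
                             sum(stats::complete.cases(bbeta[, tumors]))))
    clus <- cluster_samples(bbeta, block_ids = variable, samples = tumors,
                            element_cap = cfg$element_cap, seed = cfg$seed,
                            linkage = cfg$linkage, k = cfg$k)
    assignments <- data.frame(sample_id = names(clus$labels_at_k),
                              cluster = as.integer(clus$labels_at_k))
    utils::write.table(assignments,
                       file.path(cfg$out_dir, "cluster_assignments.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    merges <- data.frame(node = seq_len(nrow(clus$hclust$merge)),
                         child1 = clus$hclust$merge[, 1],
                         child2 = clus$hclust$merge[, 2],
                         height = clus$hclust$height)
    utils::write.table(merges, file.path(cfg$out_dir, "linkage_tree.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

    tissue_samples <- sheet$sample_id[sheet$material == "tissue"]
    fractions <- data.frame(
      sample_id = tissue_samples,
      methylated_fraction = vapply(tissue_samples, function(s) {
        methylated_fraction(bbeta, s, reference, "tissue")
      }, numeric(1)))
    utils::write.table(fractions,
                       file.path(cfg$out_dir, "methylated_fractions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    results$reference_blocks <- reference
    results$aberrant <- aberrant
    results$cluster <- clus
    results$fractions <- fractions
  }

  if (!is.null(cfg$expression)) {
    results$screen <- run_screen_stage(cfg, sheet, blocks, bbeta, tumors,
                                       normals, acfg)
  }

  if (!is.null(cfg$qmsp)) {
    pmr <- pmr_table(read_qmsp(cfg$qmsp))
    utils::write.csv(pmr, file.path(cfg$out_dir, "pmr.csv"),
                     row.names = FALSE, quote = FALSE)
    results$pmr <- pmr
  }

  pairs <- find_pairs(sheet)
  if (nrow(pairs) > 0 && length(normals) > 0) {
    universe <- normally_unmethylated_cgi_blocks(bbeta, blocks, normals,
                                                 acfg)
    calls <- lapply(seq_len(nrow(pairs)), function(i) {
      pr <- pair_sets(bbeta, pairs$primary[i], pairs$metastasis[i],
                      universe, config = acfg,
                      patient_id = pairs$patient_id[i])
      call <- classify_evolution(pr, cfg$shared_fraction_min)
      c(unclass(call),
        list(shared_blocks = intersect(pr$primary_aberrant,
                                       pr$met_aberrant),
             primary_private_blocks = setdiff(pr$primary_aberrant,
                                              pr$met_aberrant),
             met_private_blocks = setdiff(pr$met_aberrant,
                                          pr$primary_aberrant)))
    })
    names(calls) <- pairs$patient_id
    jsonlite::write_json(calls, file.path(cfg$out_dir, "evolution.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    results$evolution <- calls
  }

  run_manifest <- list(
    package = "methylscreen",
    version = as.character(utils::packageVersion("methylscreen")),
    config = cfg[order(names(cfg))]
  )
  jsonlite::write_json(run_manifest,
                       file.path(cfg$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}

pipeline_defaults <- function(config) {
  defaults <- list(
    out_dir = "methylscreen_out", seed = 1,
    meth_threshold = 0.4, unmeth_threshold = 0.2, min_tumor_count = 6,
    baseline_threshold = 0.5, induction_log2_threshold = 1,
    cell_line_meth_threshold = 0.8, n_variable_blocks = 500,
    element_cap = 20000, linkage = "complete", k = 2,
    shared_fraction_min = 0.75,
    expression = NULL, probe_gene_map = NULL, qmsp = NULL,
    msc_samples = NULL, ob_samples = NULL
  )
  unknown <- setdiff(names(config),
                     c(names(defaults),
                       c("manifest", "beta", "sample_sheet")))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  utils::modifyList(defaults, config)
}

run_screen_stage <- function(cfg, sheet, blocks, bbeta, tumors, normals,
                             acfg) {
  if (!file.exists(cfg$expression)) {
    stop("input file not found (expression): ", cfg$expression)
  }
  if (is.null(cfg$probe_gene_map)) {
    stop("expression analysis requires probe_gene_map")
  }
  expr <- normalize_75th(read_expression_matrix(cfg$expression))
  gexpr <- aggregate_genes(expr, read_probe_gene_map(cfg$probe_gene_map))
  groups <- list(msc = cfg$msc_samples, ob = cfg$ob_samples)
  baseline <- expressed_in_baseline(gexpr, groups, cfg$baseline_threshold)
  criteria <- screen_criteria(
    aberrant = acfg, baseline_threshold = cfg$baseline_threshold,
    induction_log2_threshold = cfg$induction_log2_threshold,
    cell_line_meth_threshold = cfg$cell_line_meth_threshold)
  universe <- eligible_gene_universe(blocks, bbeta, tumors, normals,
                                     baseline, rownames(gexpr), criteria)

  mocks <- sheet[sheet$group == "mock", , drop = FALSE]
  out <- list(universe = universe, per_cell_line = list())
  for (mock_id in mocks$sample_id) {
    cl <- sub("_mock$", "", mock_id)
    treated_id <- paste0(cl, "_aza")
    if (!treated_id %in% sheet$sample_id ||
        !all(c(mock_id, treated_id) %in% colnames(gexpr))) next
    induction <- induction_screen(gexpr, mock_id, treated_id,
                                  cfg$induction_log2_threshold)
    screen <- run_screen(universe, bbeta, mock_id, induction, criteria)
    utils::write.table(
      screen, file.path(cfg$out_dir, paste0("screen_", cl, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    out$per_cell_line[[cl]] <- screen
  }
  screen_json <- list(
    criteria = list(
      meth_threshold = acfg$meth_threshold,
      unmeth_threshold = acfg$unmeth_threshold,
      min_tumor_count = acfg$min_tumor_count,
      baseline_threshold = cfg$baseline_threshold,
      induction_log2_threshold = cfg$induction_log2_threshold,
      cell_line_meth_threshold = cfg$cell_line_meth_threshold),
    universe_size = nrow(universe),
    candidates = lapply(out$per_cell_line, function(s) {
      s[s$passes, , drop = FALSE]
    }))
  jsonlite::write_json(screen_json, file.path(cfg$out_dir, "screen.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  out
}

find_pairs <- function(sheet) {
  prim <- sheet[sheet$group == "tumor_primary" & !is.na(sheet$patient_id), ]
  met <- sheet[sheet$group == "tumor_metastasis" &
                 !is.na(sheet$patient_id), ]
  shared <- intersect(prim$patient_id, met$patient_id)
  data.frame(
    patient_id = shared,
    primary = prim$sample_id[match(shared, prim$patient_id)],
    metastasis = met$sample_id[match(shared, met$patient_id)],
    stringsAsFactors = FALSE
  )
}
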