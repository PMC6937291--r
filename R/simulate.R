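#' Configuration for the synthetic-data generator
#'
#' Default values reproduce the structure of the study design the analysis
#' targets: a beadarray cohort of 28 primary tumors (10 of them forming a
#' high-methylation, CIMP-like subgroup) and 3 normal controls, cell lines
#' assayed mock- and demethylating-agent-treated, baseline expression in
#' 7 mesenchymal stem cell and 3 osteoblast arrays, and qMSP molecule
#' counts. Beta values are drawn from state-specific Beta distributions
#' (means near 0.05 / 0.5 / 0.85), the standard emulation of beadarray
#' bimodality; cell lines use sharper, near-binary shapes. Expression noise
#' is multiplicative log-normal. All outputs are fully determined by `seed`.
#'
#' @param seed Master seed; every simulated output derives its own named
#'   stream from it.
#' @param n_genes Number of genes on the simulated array (default 2000).
#' @param probes_per_block Range of probes per TSS200 CpG-island block
#'   (default 2 to 5).
#' @param body_probe_fraction Fraction of genes that also carry open-sea
#'   gene-body probes (default 0.3).
#' @param n_normals,n_tumors Normal and primary-tumor sample counts
#'   (defaults 3 and 28).
#' @param n_high_methylators Size of the planted high-methylation tumor
#'   subgroup (default 10).
#' @param n_cell_lines Number of cell lines, each with a mock and a treated
#'   array (default 2).
#' @param aberrant_block_fraction Fraction of genes whose promoter block is
#'   planted aberrantly methylated in the tumor cohort (default 0.02).
#' @param min_aberrant_carriers Minimum number of tumors carrying each
#'   planted aberrant block (default 8; the actual count per block is drawn
#'   uniformly between this and `n_tumors`).
#' @param high_methylator_extra_fraction Planted total fraction of
#'   normally-unmethylated CpG-island blocks methylated in a
#'   high-methylator sample (default 0.20); the shared susceptible block
#'   set is sized so carried planted-aberrant blocks plus susceptible
#'   blocks hit this rate.
#' @param n_silenced Planted methylation-silenced (and drug-reactivated)
#'   genes per cell line, drawn from the aberrant genes (default 20).
#' @param cell_line_extra_meth_rate Probability that a non-silenced
#'   aberrant block is also methylated in a cell line (default 0.3).
#' @param expressed_gene_fraction Fraction of genes expressed in the
#'   baseline cell types (default 0.30); planted silenced genes are always
#'   expressed there.
#' @param n_msc,n_ob Baseline mesenchymal-stem-cell and osteoblast sample
#'   counts (defaults 7 and 3).
#' @param baseline_expressed_level,background_level,silenced_mock_level
#'   Normalized-scale expression levels for expressed genes, background,
#'   and silenced genes in the untreated cell line (defaults 1.5, 0.05,
#'   0.02).
#' @param induction_true_fold True fold-induction of silenced genes under
#'   demethylating treatment (default 4).
#' @param expression_noise_cv Coefficient of variation of the log-normal
#'   expression noise (default 0.10).
#' @param beta_unmeth_params,beta_partial_params,beta_meth_params
#'   Beta-distribution shape pairs for tissue unmethylated / partial /
#'   methylated states (defaults `c(2, 38)`, `c(10, 10)`, `c(17, 3)`).
#' @param cl_beta_unmeth_params,cl_beta_meth_params Near-binary shapes for
#'   cell lines (defaults `c(5, 95)`, `c(90, 10)`).
#' @param noise `FALSE` replaces the Beta draws with the point masses
#'   0.05 / 0.5 / 0.85 and removes expression noise (noise-free mode).
#' @param demethylation_range Uniform range of the planted promoter-beta
#'   decrease under treatment (default `c(0.18, 0.51)`).
#' @param qmsp_poisson_scale Expected Alu molecule count per qMSP well
#'   (default 10000); `Inf` gives the noise-free limit.
#' @param qmsp_ref_meth_rate Methylated molecules per Alu molecule in the
#'   fully methylated reference (default 0.5).
#' @param pair_mode `"clonal"` or `"parallel"` generation of
#'   primary-metastasis pairs.
#' @param pair_universe_size Evaluable block universe per pair (default
#'   120).
#' @param pair_primary_aberrant Aberrant blocks in the primary (default
#'   40).
#' @param pair_extra_events Metastasis-private events added in clonal mode
#'   (default 12).
#' @param pair_ancestor_size,pair_private_events Shared ancestral set and
#'   per-lesion private events in parallel mode (defaults 20 and 20).
#' @param pair_flip_rate Per-block, per-lesion call-flip noise rate
#'   (default 0).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_genes = 2000,
                       probes_per_block = c(2, 5),
                       body_probe_fraction = 0.3,
                       n_normals = 3,
                       n_tumors = 28,
                       n_high_methylators = 10,
                       n_cell_lines = 2,
                       aberrant_block_fraction = 0.02,
                       min_aberrant_carriers = 8,
                       high_methylator_extra_fraction = 0.20,
                       n_silenced = 20,
                       cell_line_extra_meth_rate = 0.3,
                       expressed_gene_fraction = 0.30,
                       n_msc = 7,
                       n_ob = 3,
                       baseline_expressed_level = 1.5,
                       background_level = 0.05,
                       silenced_mock_level = 0.02,
                       induction_true_fold = 4,
                       expression_noise_cv = 0.10,
                       beta_unmeth_params = c(2, 38),
                       beta_partial_params = c(10, 10),
                       beta_meth_params = c(17, 3),
                       cl_beta_unmeth_params = c(5, 95),
                       cl_beta_meth_params = c(90, 10),
                       noise = TRUE,
                       demethylation_range = c(0.18, 0.51),
                       qmsp_poisson_scale = 10000,
                       qmsp_ref_meth_rate = 0.5,
                       pair_mode = c("clonal", "parallel"),
                       pair_universe_size = 120,
                       pair_primary_aberrant = 40,
                       pair_extra_events = 12,
                       pair_ancestor_size = 20,
                       pair_private_events = 20,
                       pair_flip_rate = 0) {
  pair_mode <- match.arg(pair_mode)
  cfg <- as.list(environment())
  fracs <- c(body_probe_fraction, aberrant_block_fraction,
             high_methylator_extra_fraction, expressed_gene_fraction,
             cell_line_extra_meth_rate, pair_flip_rate)
  stopifnot(all(fracs >= 0), all(fracs <= 1),
            n_genes >= 0, n_tumors >= 1 || n_genes == 0,
            n_high_methylators <= n_tumors,
            min_aberrant_carriers <= n_tumors,
            expression_noise_cv >= 0, induction_true_fold > 0,
            qmsp_ref_meth_rate > 0,
            pair_primary_aberrant + pair_extra_events <= pair_universe_size,
            pair_ancestor_size + 2 * pair_private_events <=
              pair_universe_size)
  structure(cfg, class = "sim_config")
}

#' Simulate a probe-annotation manifest
#'
#' Each gene receives a TSS200 CpG-island block of 2-5 probes; a fraction
#' of genes additionally carry 1-3 open-sea gene-body probes. Chromosomes
#' and positions are drawn over the autosomes. Byte-identical across calls
#' with the same configuration.
#'
#' @param config [sim_config()].
#' @return Probe records as returned by [load_manifest()].
#' @export
simulate_manifest <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  if (n == 0) {
    return(validate_manifest(data.frame(
      probe_id = character(), chrom = character(), pos = integer(),
      gene = character(), tss_relation = character(),
      cgi_relation = character(), cgi_id = character(),
      stringsAsFactors = FALSE)))
  }
  with_seed(derive_seed(config$seed, "manifest"), {
    genes <- sprintf("G%04d", seq_len(n))
    chrom <- sample(AUTOSOMES, n, replace = TRUE)
    base <- sample.int(2e8, n)
    k_tss <- sample(seq(config$probes_per_block[1],
                        config$probes_per_block[2]), n, replace = TRUE)
    has_body <- stats::runif(n) < config$body_probe_fraction
    k_body <- ifelse(has_body, sample(1:3, n, replace = TRUE), 0L)

    gene_rep <- rep(seq_len(n), k_tss + k_body)
    is_tss <- unlist(lapply(seq_len(n), function(i) {
      c(rep(TRUE, k_tss[i]), rep(FALSE, k_body[i]))
    }), use.names = FALSE)
    offset <- unlist(lapply(seq_len(n), function(i) {
      c(seq_len(k_tss[i]) * 20L, 2000L + seq_len(k_body[i]) * 500L)
    }), use.names = FALSE)
    df <- data.frame(
      probe_id = sprintf("cg%07d", seq_along(gene_rep)),
      chrom = chrom[gene_rep],
      pos = base[gene_rep] + offset,
      gene = genes[gene_rep],
      tss_relation = ifelse(is_tss, "TSS200", "Body"),
      cgi_relation = ifelse(is_tss, "Island", "OpenSea"),
      cgi_id = ifelse(is_tss, sprintf("CGI%05d", gene_rep), NA_character_),
      stringsAsFactors = FALSE
    )
    validate_manifest(df)
  })
}

#' Simulate a methylation beadarray cohort with planted ground truth
#'
#' Generates a probe-level beta matrix for normal controls, primary tumors
#' (with a planted high-methylation subgroup) and cell lines (mock- and
#' demethylating-agent-treated), together with the planted truth. Promoter
#' blocks are unmethylated in normals; planted aberrant blocks are
#' methylated in a drawn carrier set of tumors; a shared "susceptible"
#' block set is methylated in every high-methylator; gene-body blocks are
#' partially methylated everywhere. Cell lines are methylated at their
#' planted silenced genes (plus a random fraction of other aberrant
#' blocks), and the treated array shows a planted promoter-beta decrease at
#' silenced blocks.
#'
#' @param config [sim_config()].
#' @param manifest Probe records from [simulate_manifest()] (regenerated
#'   when omitted).
#' @return List with `beta` (probe-level matrix), `samples` (sample sheet),
#'   `blocks` (assembled blocks) and `truth` (see Details). `truth` is a
#'   list with the planted gene/block sets, per-block tumor carrier sets,
#'   high-methylator sample ids, per-cell-line silenced genes and
#'   demethylation deltas, and the normally-unmethylated reference block
#'   set.
#' @export
simulate_beta_cohort <- function(config, manifest = simulate_manifest(config)) {
  stopifnot(inherits(config, "sim_config"))
  blocks <- assemble_blocks(manifest)
  tss <- blocks[blocks$tss_relation == "TSS200" &
                  blocks$cgi_relation == "Island" & !is.na(blocks$gene), ]
  gene_block <- stats::setNames(tss$block_id, tss$gene)

  normals <- sprintf("N%02d", seq_len(config$n_normals))
  tumors <- sprintf("T%02d", seq_len(config$n_tumors))
  cl_ids <- sprintf("CL%d", seq_len(config$n_cell_lines))
  cl_mock <- paste0(cl_ids, "_mock")
  cl_aza <- paste0(cl_ids, "_aza")

  with_seed(derive_seed(config$seed, "beta_cohort"), {
    n_aberrant <- round(config$aberrant_block_fraction * config$n_genes)
    aberrant_genes <- sort(sample(names(gene_block), n_aberrant))
    aberrant_blocks <- unname(gene_block[aberrant_genes])
    carriers <- lapply(seq_len(n_aberrant), function(i) {
      size <- sample(seq(config$min_aberrant_carriers, config$n_tumors), 1)
      sort(sample(tumors, size))
    })
    names(carriers) <- aberrant_blocks
    high_samples <- sort(sample(tumors, config$n_high_methylators))

    # size the shared susceptible set so that carried aberrant blocks plus
    # susceptible blocks reach the planted total methylation rate
    n_tss <- nrow(tss)
    mean_carried <- if (config$n_tumors > 0)
      sum(lengths(carriers)) / config$n_tumors else 0
    n_susceptible <- if (config$n_high_methylators > 0) {
      max(0, round(config$high_methylator_extra_fraction * n_tss -
                     mean_carried))
    } else 0
    susceptible_blocks <- sort(sample(setdiff(tss$block_id, aberrant_blocks),
                                      n_susceptible))

    silenced <- lapply(cl_ids, function(cl) {
      sort(sample(aberrant_genes, min(config$n_silenced, n_aberrant)))
    })
    names(silenced) <- cl_ids
    cl_extra_meth <- lapply(cl_ids, function(cl) {
      pool <- setdiff(aberrant_blocks, unname(gene_block[silenced[[cl]]]))
      sort(pool[stats::runif(length(pool)) <
                  config$cell_line_extra_meth_rate])
    })
    names(cl_extra_meth) <- cl_ids

    # per-block, per-sample state codes: 1 unmeth, 2 partial, 3 meth
    all_mock <- c(normals, tumors, cl_mock)
    S <- matrix(1L, nrow = nrow(blocks), ncol = length(all_mock),
                dimnames = list(blocks$block_id, all_mock))
    body_blocks <- blocks$block_id[!(blocks$block_id %in% tss$block_id)]
    S[body_blocks, ] <- 2L
    for (b in aberrant_blocks) S[b, carriers[[b]]] <- 3L
    if (length(susceptible_blocks) > 0 && length(high_samples) > 0) {
      S[susceptible_blocks, high_samples] <- 3L
    }
    for (i in seq_along(cl_ids)) {
      meth_blocks <- c(unname(gene_block[silenced[[i]]]), cl_extra_meth[[i]])
      S[meth_blocks, cl_mock[i]] <- 3L
    }

    # expand block states to probes and draw beta values
    probe_block <- rep(seq_len(nrow(blocks)), lengths(blocks$probe_ids))
    probe_ids <- unlist(blocks$probe_ids, use.names = FALSE)
    # the simulated manifest maps each probe to one block, so this is a
    # bijection onto manifest probes
    PS <- S[probe_block, , drop = FALSE]
    material <- ifelse(all_mock %in% cl_mock, "cell_line", "tissue")
    beta <- matrix(NA_real_, nrow = length(probe_ids),
                   ncol = length(all_mock),
                   dimnames = list(probe_ids, all_mock))
    for (j in seq_along(all_mock)) {
      beta[, j] <- draw_beta(PS[, j], material[j], config)
    }

    # treated cell-line arrays: planted demethylation at silenced blocks
    deltas <- vector("list", length(cl_ids))
    names(deltas) <- cl_ids
    treated <- matrix(NA_real_, nrow = length(probe_ids),
                      ncol = length(cl_aza),
                      dimnames = list(probe_ids, cl_aza))
    for (i in seq_along(cl_ids)) {
      g <- silenced[[i]]
      d <- stats::runif(length(g), config$demethylation_range[1],
                        config$demethylation_range[2])
      names(d) <- g
      deltas[[i]] <- d
      col <- beta[, cl_mock[i]]
      probe_delta <- rep(0, length(probe_ids))
      for (gg in g) {
        idx <- probe_block == match(gene_block[[gg]], blocks$block_id)
        probe_delta[idx] <- d[[gg]]
      }
      treated[, i] <- pmin(pmax(col - probe_delta, 0), 1)
    }
    beta <- cbind(beta, treated)

    samples <- data.frame(
      sample_id = colnames(beta),
      material = c(rep("tissue", length(normals) + length(tumors)),
                   rep("cell_line", 2 * length(cl_ids))),
      group = c(rep("normal", length(normals)),
                rep("tumor_primary", length(tumors)),
                rep("mock", length(cl_ids)), rep("treated", length(cl_ids))),
      patient_id = NA_character_,
      stringsAsFactors = FALSE
    )

    truth <- list(
      genes = names(gene_block),
      gene_block = gene_block,
      aberrant_genes = aberrant_genes,
      aberrant_blocks = aberrant_blocks,
      carriers = carriers,
      carrier_counts = stats::setNames(lengths(carriers), aberrant_blocks),
      high_samples = high_samples,
      susceptible_blocks = susceptible_blocks,
      silenced_genes = silenced,
      demethylation_delta = deltas,
      reference_blocks = sort(tss$block_id),
      normals = normals,
      tumors = tumors,
      cell_lines = data.frame(cell_line = cl_ids, mock = cl_mock,
                              aza = cl_aza, stringsAsFactors = FALSE)
    )
    list(beta = beta, samples = samples, blocks = blocks, truth = truth)
  })
}

draw_beta <- function(state, material, config) {
  if (!config$noise) {
    return(c(0.05, 0.5, 0.85)[state])
  }
  shapes <- if (material == "cell_line") {
    list(config$cl_beta_unmeth_params, config$beta_partial_params,
         config$cl_beta_meth_params)
  } else {
    list(config$beta_unmeth_params, config$beta_partial_params,
         config$beta_meth_params)
  }
  out <- numeric(length(state))
  for (s in 1:3) {
    idx <- state == s
    if (any(idx)) {
      out[idx] <- stats::rbeta(sum(idx), shapes[[s]][1], shapes[[s]][2])
    }
  }
  out
}

#' Planted aberrant blocks implied by the simulation truth
#'
#' The set of blocks that are, by construction, unmethylated in every
#' normal and methylated in at least `min_tumor_count` tumors: planted
#' aberrant blocks whose carrier set is large enough, plus the
#' high-methylator susceptible blocks when the subgroup itself reaches the
#' count.
#'
#' @param truth `truth` element of [simulate_beta_cohort()].
#' @param min_tumor_count Tumor-count threshold (default 6).
#' @return Sorted character vector of block ids.
#' @export
true_aberrant_blocks <- function(truth, min_tumor_count = 6) {
  out <- truth$aberrant_blocks[truth$carrier_counts >= min_tumor_count]
  if (length(truth$high_samples) >= min_tumor_count) {
    out <- c(out, truth$susceptible_blocks)
  }
  sort(out)
}

#' Simulate baseline and cell-line expression arrays
#'
#' Generates a probe-level expression matrix for mesenchymal-stem-cell and
#' osteoblast baseline samples plus mock/treated arrays of each cell line
#' in the cohort truth. A planted fraction of genes (always including the
#' silenced genes) is expressed in the baseline; silenced genes sit near
#' the detection floor in the mock-treated cell line and are raised
#' `induction_true_fold`-fold in the treated array. Values carry
#' multiplicative log-normal noise and an arbitrary per-sample scale
#' factor, so [normalize_75th()] is required before analysis.
#'
#' @param config [sim_config()].
#' @param truth `truth` element of [simulate_beta_cohort()].
#' @return List with `expr` (probe-level unnormalized matrix), `probe_gene`
#'   (mapping `data.frame`), `baseline_groups` (named list of MSC and OB
#'   sample ids), `expressed_genes` (planted baseline-expressed set).
#' @export
simulate_expression <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  genes <- truth$genes
  with_seed(derive_seed(config$seed, "expression"), {
    expressed <- sort(union(
      sample(genes, round(config$expressed_gene_fraction * length(genes))),
      unlist(truth$silenced_genes, use.names = FALSE)))

    msc <- sprintf("MSC_%d", seq_len(config$n_msc))
    ob <- sprintf("OB_%d", seq_len(config$n_ob))
    cl <- truth$cell_lines
    samples <- c(msc, ob, cl$mock, cl$aza)

    level <- matrix(config$background_level, nrow = length(genes),
                    ncol = length(samples),
                    dimnames = list(genes, samples))
    level[expressed, c(msc, ob)] <- config$baseline_expressed_level
    for (i in seq_len(nrow(cl))) {
      mock_col <- cl$mock[i]
      aza_col <- cl$aza[i]
      on_genes <- setdiff(expressed, truth$silenced_genes[[i]])
      level[on_genes, c(mock_col, aza_col)] <- config$baseline_expressed_level
      sil <- truth$silenced_genes[[i]]
      level[sil, mock_col] <- config$silenced_mock_level
      level[sil, aza_col] <- config$silenced_mock_level *
        config$induction_true_fold
    }

    n_probes <- sample(1:2, length(genes), replace = TRUE)
    probe_gene <- data.frame(
      probe_id = sprintf("EP%05d", seq_len(sum(n_probes))),
      gene = rep(genes, n_probes),
      stringsAsFactors = FALSE
    )
    expr <- level[probe_gene$gene, , drop = FALSE]
    rownames(expr) <- probe_gene$probe_id
    if (config$noise && config$expression_noise_cv > 0) {
      sdlog <- sqrt(log(1 + config$expression_noise_cv^2))
      noise <- matrix(stats::rlnorm(length(expr), -sdlog^2 / 2, sdlog),
                      nrow = nrow(expr))
      expr <- expr * noise
    }
    scale <- stats::runif(ncol(expr), 50, 150)
    expr <- sweep(expr, 2, scale, "*")
    list(expr = expr, probe_gene = probe_gene,
         baseline_groups = list(msc = msc, ob = ob),
         expressed_genes = expressed)
  })
}

#' Simulate qMSP molecule counts for a known PMR
#'
#' Draws Poisson molecule counts for a sample with known true PMR and for
#' the fully methylated reference, consistent with `qmsp_ref_meth_rate`
#' methylated molecules per Alu molecule in the reference. With
#' `qmsp_poisson_scale = Inf` the expected counts are returned exactly
#' (noise-free limit).
#'
#' @param config [sim_config()].
#' @param true_pmr True percentage of methylated reference (>= 0).
#' @param n_replicates Wells per sample and per reference (default 1).
#' @param sample_id,target_id Identifiers for the output table.
#' @return Measurement `data.frame` in the layout of [read_qmsp()].
#' @export
simulate_qmsp <- function(config, true_pmr, n_replicates = 1,
                          sample_id = "S1", target_id = "TARGET1") {
  stopifnot(inherits(config, "sim_config"), true_pmr >= 0)
  scale <- config$qmsp_poisson_scale
  r <- config$qmsp_ref_meth_rate
  if (!is.finite(scale)) {
    s <- 1e6
    df <- data.frame(
      sample_id = c(rep(sample_id, n_replicates), rep("REF", n_replicates)),
      target_id = target_id,
      meth_molecules = c(rep(s * r * true_pmr / 100, n_replicates),
                         rep(s * r, n_replicates)),
      alu_molecules = rep(s, 2 * n_replicates),
      is_reference = rep(c(FALSE, TRUE), each = n_replicates),
      stringsAsFactors = FALSE
    )
    return(df)
  }
  with_seed(derive_seed(config$seed, paste0("qmsp_", sample_id)), {
    data.frame(
      sample_id = c(rep(sample_id, n_replicates), rep("REF", n_replicates)),
      target_id = target_id,
      meth_molecules = c(stats::rpois(n_replicates,
                                      scale * r * true_pmr / 100),
                         stats::rpois(n_replicates, scale * r)),
      alu_molecules = stats::rpois(2 * n_replicates, scale),
      is_reference = rep(c(FALSE, TRUE), each = n_replicates),
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate a primary-metastasis methylation pair
#'
#' Clonal mode plants the metastasis set as the primary set plus extra
#' private events; parallel mode draws primary and metastasis
#' independently as an ancestral set plus per-lesion private events.
#' Optional call-flip noise toggles each universe block's membership in
#' each lesion independently with probability `pair_flip_rate`, emulating
#' borderline beta calls.
#'
#' @param config [sim_config()].
#' @param pair_mode Override `config$pair_mode`.
#' @param patient_id Identifier carried into the pair.
#' @param seed Override the stream seed (handy when drawing many pairs).
#' @return List with `pair` (a [methylation_pair()], after noise) and
#'   `truth` (list with `mode` and the noise-free `primary_true`,
#'   `met_true` sets).
#' @export
simulate_pair <- function(config, pair_mode = config$pair_mode,
                          patient_id = "P1", seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  pair_mode <- match.arg(pair_mode, c("clonal", "parallel"))
  if (is.null(seed)) {
    seed <- derive_seed(config$seed, paste0("pair_", patient_id))
  }
  with_seed(seed, {
    universe <- sprintf("blk%04d", seq_len(config$pair_universe_size))
    if (pair_mode == "clonal") {
      p0 <- sort(sample(universe, config$pair_primary_aberrant))
      m0 <- sort(union(p0, sample(setdiff(universe, p0),
                                  config$pair_extra_events)))
    } else {
      anc <- sample(universe, config$pair_ancestor_size)
      rest <- setdiff(universe, anc)
      p0 <- sort(union(anc, sample(rest, config$pair_private_events)))
      m0 <- sort(union(anc, sample(rest, config$pair_private_events)))
    }
    flip <- function(members) {
      inset <- universe %in% members
      flips <- stats::runif(length(universe)) < config$pair_flip_rate
      universe[xor(inset, flips)]
    }
    p <- if (config$pair_flip_rate > 0) flip(p0) else p0
    m <- if (config$pair_flip_rate > 0) flip(m0) else m0
    list(pair = methylation_pair(p, m, universe, patient_id = patient_id),
         truth = list(mode = pair_mode, primary_true = p0, met_true = m0))
  })
}

#' Write a simulated cohort to disk in the package's file dialects
#'
#' Emits the manifest CSV, beta TSV, sample sheet TSV, expression TSV,
#' probe-to-gene CSV and a `ground_truth.json` into a directory, ready for
#' [run_pipeline()].
#'
#' @param cohort [simulate_beta_cohort()] result.
#' @param expression [simulate_expression()] result (optional).
#' @param dir Output directory (created if needed).
#' @param manifest Probe records used for the cohort.
#' @return `dir`, invisibly.
#' @export
save_simulation <- function(cohort, expression = NULL, dir,
                            manifest = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(manifest)) {
    write_manifest(manifest, file.path(dir, "manifest.csv"))
  }
  write_value_matrix(cohort$beta, file.path(dir, "beta.tsv"))
  write_sample_sheet(cohort$samples, file.path(dir, "samples.tsv"))
  truth <- cohort$truth
  if (!is.null(expression)) {
    write_value_matrix(expression$expr, file.path(dir, "expression.tsv"),
                       id_col = "probe_id")
    utils::write.csv(expression$probe_gene,
                     file.path(dir, "probe_gene.csv"), row.names = FALSE,
                     quote = FALSE)
    truth$expressed_genes <- expression$expressed_genes
    truth$baseline_groups <- expression$baseline_groups
  }
  truth$carriers <- NULL  # bulky; counts retained
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
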