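#' Criteria for the methylation-silencing screen
#'
#' Bundles the thresholds of the integrated chemical-genomic screen:
#' which blocks count as aberrantly methylated in tumors, what "expressed in
#' the baseline cell types" means, how strong re-activation by the
#' demethylating agent must be, and whether the screened cell line itself
#' must be methylated at the gene's promoter block.
#'
#' @param aberrant [aberrant_config()] for the tumor-cohort methylation
#'   filter.
#' @param baseline_threshold Normalized-signal threshold for baseline
#'   expression (default 0.5).
#' @param induction_log2_threshold Log2-ratio threshold for induction
#'   (default 1, i.e. two-fold).
#' @param cell_line_meth_threshold Beta at or above which a cell-line block
#'   is methylated (default 0.8, the cell-line methylated-state bound).
#' @param require_cell_line_methylated Require the screened cell line to be
#'   methylated at the gene's block (default `TRUE`); set `FALSE` for a pure
#'   induction screen.
#' @param restrict_to_tss200_cgi Restrict to blocks within 200 bp of a TSS
#'   on a CpG island (default `TRUE`).
#' @return A list of class `screen_criteria`.
#' @export
screen_criteria <- function(aberrant = aberrant_config(),
                            baseline_threshold = 0.5,
                            induction_log2_threshold = 1,
                            cell_line_meth_threshold = 0.8,
                            require_cell_line_methylated = TRUE,
                            restrict_to_tss200_cgi = TRUE) {
  stopifnot(inherits(aberrant, "aberrant_config"),
            baseline_threshold >= 0,
            cell_line_meth_threshold > 0, cell_line_meth_threshold <= 1)
  structure(list(aberrant = aberrant,
                 baseline_threshold = baseline_threshold,
                 induction_log2_threshold = induction_log2_threshold,
                 cell_line_meth_threshold = cell_line_meth_threshold,
                 require_cell_line_methylated = require_cell_line_methylated,
                 restrict_to_tss200_cgi = restrict_to_tss200_cgi),
            class = "screen_criteria")
}

#' Gene universe eligible for the methylation-silencing screen
#'
#' Builds the set of genes that can, in principle, be methylation-silenced
#' and assayed: genes with a TSS200 CpG-island block that is unmethylated in
#' all normal samples and methylated in at least `min_tumor_count` tumors,
#' that are expressed in the baseline cell types, and whose expression is
#' evaluable on the expression platform. For genes with several qualifying
#' blocks, the block methylated in the most tumors represents the gene
#' (ties broken by block id).
#'
#' @param blocks Blocks from [assemble_blocks()].
#' @param bbeta Block-level beta matrix of the tissue cohort.
#' @param tumors,normals Sample-id vectors.
#' @param baseline_genes Genes expressed in the baseline cell types
#'   ([expressed_in_baseline()]).
#' @param evaluable_genes Genes measurable on the expression platform
#'   (e.g. `rownames` of the gene-level expression matrix).
#' @param criteria [screen_criteria()].
#' @return `data.frame` of class `gene_universe` with columns `gene`,
#'   `block_id`, `n_methylated_tumors`, sorted by gene.
#' @export
eligible_gene_universe <- function(blocks, bbeta, tumors, normals,
                                   baseline_genes, evaluable_genes,
                                   criteria = screen_criteria()) {
  if (length(baseline_genes) == 0) {
    stop("baseline expressed-gene set is empty")
  }
  sel <- !is.na(blocks$gene)
  if (criteria$restrict_to_tss200_cgi) {
    sel <- sel & blocks$tss_relation == "TSS200" &
      blocks$cgi_relation == "Island"
  }
  cand <- blocks[sel, c("block_id", "gene"), drop = FALSE]
  cand <- cand[cand$block_id %in% rownames(bbeta), , drop = FALSE]
  calls <- call_aberrant_blocks(bbeta, tumors, normals,
                                config = criteria$aberrant,
                                block_ids = cand$block_id)
  hits <- merge(calls, cand, by = "block_id")
  hits <- hits[hits$gene %in% baseline_genes &
                 hits$gene %in% evaluable_genes, , drop = FALSE]
  # representative block per gene: most methylated tumors, then block id
  hits <- hits[order(hits$gene, -hits$n_methylated_tumors, hits$block_id), ,
               drop = FALSE]
  hits <- hits[!duplicated(hits$gene), , drop = FALSE]
  out <- data.frame(gene = hits$gene, block_id = hits$block_id,
                    n_methylated_tumors = hits$n_methylated_tumors,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("gene_universe", "data.frame")
  out
}

#' Run the methylation-silencing screen on one cell line
#'
#' Intersects the eligible gene universe with the cell line's evidence: the
#' gene's promoter block must be methylated in the cell line (beta at or
#' above `cell_line_meth_threshold`, unless that requirement is disabled)
#' and the gene must be induced by demethylating treatment. Per-criterion
#' evidence is reported for every universe gene; candidates are the rows
#' with `passes = TRUE`.
#'
#' @param universe [eligible_gene_universe()] result.
#' @param cell_line_bbeta Block-level beta matrix containing the cell line.
#' @param cell_line Sample id of the (mock-treated) cell line.
#' @param induction [induction_screen()] result for the same cell line.
#' @param criteria [screen_criteria()].
#' @return `data.frame` with columns `gene`, `block_id`,
#'   `n_methylated_tumors`, `cell_line_beta`, `cell_line_methylated`,
#'   `log2_induction`, `induced`, `passes`, sorted by decreasing
#'   `log2_induction` then gene symbol.
#' @export
run_screen <- function(universe, cell_line_bbeta, cell_line, induction,
                       criteria = screen_criteria()) {
  stopifnot(inherits(universe, "gene_universe"))
  if (!cell_line %in% colnames(cell_line_bbeta)) {
    stop("cell line ", cell_line, " absent from block beta matrix")
  }
  out <- as.data.frame(universe)
  out <- merge(out, induction[c("gene", "log2_ratio", "induced")],
               by = "gene")
  names(out)[names(out) == "log2_ratio"] <- "log2_induction"
  out$induced <- out$log2_induction >= criteria$induction_log2_threshold
  clb <- cell_line_bbeta[out$block_id, cell_line]
  out$cell_line_beta <- as.numeric(clb)
  out$cell_line_methylated <- !is.na(clb) &
    clb >= criteria$cell_line_meth_threshold
  out$passes <- out$induced &
    (!criteria$require_cell_line_methylated | out$cell_line_methylated)
  out <- out[order(-out$log2_induction, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out[c("gene", "block_id", "n_methylated_tumors", "cell_line_beta",
        "cell_line_methylated", "log2_induction", "induced", "passes")]
}

#' Promoter demethylation between matched samples
#'
#' Reports the decrease in promoter-block beta between a matched pair of
#' samples (mock versus demethylating treatment, or untreated versus treated
#' xenograft), in percentage points of methylation.
#'
#' @param bbeta Block-level beta matrix containing both samples.
#' @param before,after Sample ids of the matched pair.
#' @param universe [eligible_gene_universe()] result (or any `data.frame`
#'   with `gene` and `block_id`) naming the genes' promoter blocks.
#' @param genes Genes to report (default all genes in `universe`).
#' @return `data.frame` with columns `gene`, `block_id`, `beta_before`,
#'   `beta_after`, `delta_pp` (percentage points of demethylation).
#' @export
demethylation_delta <- function(bbeta, before, after, universe,
                                genes = universe$gene) {
  missing_samples <- setdiff(c(before, after), colnames(bbeta))
  if (length(missing_samples) > 0) {
    stop("sample(s) absent from block beta matrix: ",
         paste(missing_samples, collapse = ", "))
  }
  stopifnot(length(before) == 1, length(after) == 1)
  sel <- universe[universe$gene %in% genes, c("gene", "block_id"),
                  drop = FALSE]
  b0 <- bbeta[sel$block_id, before]
  b1 <- bbeta[sel$block_id, after]
  data.frame(gene = sel$gene, block_id = sel$block_id,
             beta_before = as.numeric(b0), beta_after = as.numeric(b1),
             delta_pp = as.numeric(b0 - b1) * 100,
             row.names = NULL, stringsAsFactors = FALSE)
}
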