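#' Normalize an expression matrix to a 75th percentile of 1.0
#'
#' Divides each sample column by its 75th percentile so that the 75th
#' percentile of signal intensity of all probes equals 1.0 in every sample —
#' the scaling convention of single-color expression arrays. Percentiles use
#' linear interpolation between order statistics (R's default type-7
#' quantile). The operation is idempotent.
#'
#' @param expr Probe-level matrix of nonnegative signals, probes in rows.
#' @return The normalized matrix, with attribute `normalized = TRUE`.
#' @export
normalize_75th <- function(expr) {
  stopifnot(is.matrix(expr))
  if (min(expr, na.rm = TRUE) < 0) {
    stop("expression signals must be nonnegative")
  }
  q <- apply(expr, 2, stats::quantile, probs = 0.75, na.rm = TRUE,
             names = FALSE, type = 7)
  if (any(!is.finite(q)) || any(q == 0)) {
    bad <- colnames(expr)[!is.finite(q) | q == 0]
    stop("75th percentile is zero or undefined for sample(s): ",
         paste(bad, collapse = ", "))
  }
  out <- sweep(expr, 2, q, "/")
  attr(out, "normalized") <- TRUE
  out
}

#' Aggregate probe-level expression to gene level
#'
#' A gene's expression level is the mean signal of all its probes. Probes
#' absent from the mapping, and genes without any probe in the matrix, do
#' not appear in the output.
#'
#' @param expr Normalized probe-level matrix.
#' @param probe_gene `data.frame` with columns `probe_id`, `gene`.
#' @return Gene-level matrix (genes in rows, sorted by gene symbol), with
#'   attribute `normalized` carried over.
#' @export
aggregate_genes <- function(expr, probe_gene) {
  if (nrow(probe_gene) == 0) {
    stop("probe-to-gene mapping is empty")
  }
  stopifnot(all(c("probe_id", "gene") %in% names(probe_gene)))
  map <- probe_gene[probe_gene$probe_id %in% rownames(expr), , drop = FALSE]
  if (nrow(map) == 0) {
    stop("no probes of the mapping are present in the expression matrix")
  }
  sub <- expr[map$probe_id, , drop = FALSE]
  sums <- rowsum(sub, map$gene)
  counts <- as.vector(table(map$gene)[rownames(sums)])
  out <- sums / counts
  out <- out[order(rownames(out)), , drop = FALSE]
  attr(out, "normalized") <- attr(expr, "normalized")
  out
}

#' Genes expressed in every baseline cell type
#'
#' A gene counts as expressed when its mean normalized signal reaches
#' `threshold` in each baseline group (e.g. mesenchymal stem cells AND
#' osteoblasts, the presumed cells of origin whose expressed genes are the
#' candidates for methylation-silencing in tumors).
#'
#' @param gene_expr Gene-level normalized matrix.
#' @param baseline_groups Named list of nonempty sample-id vectors, one per
#'   baseline cell type.
#' @param threshold Normalized-signal threshold (default 0.5).
#' @return Sorted character vector of gene symbols.
#' @export
expressed_in_baseline <- function(gene_expr, baseline_groups,
                                  threshold = 0.5) {
  if (length(baseline_groups) == 0) {
    stop("at least one baseline group is required")
  }
  if (any(lengths(baseline_groups) == 0)) {
    stop("baseline group(s) empty: ",
         paste(names(baseline_groups)[lengths(baseline_groups) == 0],
               collapse = ", "))
  }
  stopifnot(all(unlist(baseline_groups) %in% colnames(gene_expr)))
  ok <- rep(TRUE, nrow(gene_expr))
  for (grp in baseline_groups) {
    ok <- ok & rowMeans(gene_expr[, grp, drop = FALSE]) >= threshold
  }
  sort(rownames(gene_expr)[ok])
}

#' Screen for genes up-regulated by demethylating treatment
#'
#' Computes per-gene `log2(treated / mock)` ratios between a mock-treated
#' and a 5-aza-2'-deoxycytidine-treated sample of the same cell line, on
#' values floored at `floor` to keep ratios finite near the detection limit,
#' and flags genes induced at or above `log2_threshold` (default 1, i.e.
#' two-fold).
#'
#' @param gene_expr Gene-level normalized matrix.
#' @param mock,treated Sample ids (vectors are averaged as replicates).
#' @param log2_threshold Induction threshold on the log2 ratio (default 1).
#' @param floor Signal floor on the normalized scale (default 0.01).
#' @return `data.frame` with columns `gene`, `mock`, `treated`,
#'   `log2_ratio`, `induced`, in the row order of `gene_expr`.
#' @export
induction_screen <- function(gene_expr, mock, treated, log2_threshold = 1,
                             floor = 0.01) {
  missing_samples <- setdiff(c(mock, treated), colnames(gene_expr))
  if (length(missing_samples) > 0) {
    stop("sample(s) absent from expression matrix: ",
         paste(missing_samples, collapse = ", "))
  }
  m <- rowMeans(gene_expr[, mock, drop = FALSE])
  t <- rowMeans(gene_expr[, treated, drop = FALSE])
  lr <- log2(pmax(t, floor) / pmax(m, floor))
  data.frame(gene = rownames(gene_expr), mock = m, treated = t,
             log2_ratio = lr, induced = lr >= log2_threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}
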