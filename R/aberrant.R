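#' Configuration for aberrant-methylation calling
#'
#' @param meth_threshold Beta at or above which a tissue block counts as
#'   methylated (default 0.4).
#' @param unmeth_threshold Beta below which a block counts as unmethylated
#'   (default 0.2).
#' @param min_tumor_count Minimum number of tumors methylated at a block for
#'   it to be called aberrant; the default 6 operationalizes "more than 5 of
#'   28 primary tumors".
#' @param normal_rule Rule for normal controls; only
#'   `"all_normals_unmethylated"` is defined: every normal sample must be
#'   below `unmeth_threshold`.
#' @return A list of class `aberrant_config`.
#' @export
aberrant_config <- function(meth_threshold = 0.4, unmeth_threshold = 0.2,
                            min_tumor_count = 6,
                            normal_rule = "all_normals_unmethylated") {
  stopifnot(unmeth_threshold > 0, unmeth_threshold < meth_threshold,
            meth_threshold <= 1, min_tumor_count >= 1)
  normal_rule <- match.arg(normal_rule, "all_normals_unmethylated")
  structure(list(meth_threshold = meth_threshold,
                 unmeth_threshold = unmeth_threshold,
                 min_tumor_count = as.integer(min_tumor_count),
                 normal_rule = normal_rule),
            class = "aberrant_config")
}

#' Blocks on CpG islands unmethylated in every normal sample
#'
#' The reference set for aberrant-methylation analysis: CpG-island blocks
#' whose beta is below the unmethylated threshold in all normal controls.
#' Blocks with a missing value in any normal sample are excluded (the rule
#' cannot be verified for them).
#'
#' @param bbeta Block-level beta matrix from [block_beta()].
#' @param blocks Blocks from [assemble_blocks()] (supplies CGI annotation).
#' @param normals Character vector of normal sample ids.
#' @param config [aberrant_config()].
#' @return Character vector of block ids.
#' @export
normally_unmethylated_cgi_blocks <- function(bbeta, blocks, normals,
                                             config = aberrant_config()) {
  if (length(normals) == 0) {
    stop("at least one normal sample is required")
  }
  stopifnot(all(normals %in% colnames(bbeta)))
  island <- blocks$block_id[blocks$cgi_relation == "Island"]
  island <- intersect(island, rownames(bbeta))
  nb <- bbeta[island, normals, drop = FALSE]
  ok <- rowSums(nb < config$unmeth_threshold) == length(normals) &
    !apply(is.na(nb), 1, any)
  ok[is.na(ok)] <- FALSE
  sort(island[ok])
}

#' Call aberrantly methylated blocks in tumors versus normals
#'
#' A block is aberrantly methylated when it is unmethylated
#' (beta < `unmeth_threshold`) in every normal sample and methylated
#' (beta >= `meth_threshold`) in at least `min_tumor_count` tumor samples.
#' The number of methylated tumors is reported per qualifying block, along
#' with the maximum beta observed across normals.
#'
#' @param bbeta Block-level beta matrix.
#' @param tumors,normals Disjoint, nonempty character vectors of sample ids.
#' @param config [aberrant_config()].
#' @param block_ids Optional subset of blocks to test (default all rows).
#' @return `data.frame` with columns `block_id`, `n_methylated_tumors`,
#'   `normal_max_beta`, sorted by `block_id`.
#' @export
call_aberrant_blocks <- function(bbeta, tumors, normals,
                                 config = aberrant_config(),
                                 block_ids = rownames(bbeta)) {
  if (length(tumors) == 0) stop("tumor sample set is empty")
  if (length(normals) == 0) stop("normal sample set is empty")
  if (length(intersect(tumors, normals)) > 0) {
    stop("tumor and normal sample sets must be disjoint")
  }
  stopifnot(all(c(tumors, normals) %in% colnames(bbeta)),
            all(block_ids %in% rownames(bbeta)))
  nb <- bbeta[block_ids, normals, drop = FALSE]
  tb <- bbeta[block_ids, tumors, drop = FALSE]
  normal_ok <- rowSums(nb < config$unmeth_threshold) == length(normals)
  normal_ok[is.na(normal_ok)] <- FALSE
  n_meth <- rowSums(tb >= config$meth_threshold, na.rm = TRUE)
  hit <- normal_ok & n_meth >= config$min_tumor_count
  out <- data.frame(
    block_id = block_ids[hit],
    n_methylated_tumors = as.integer(n_meth[hit]),
    normal_max_beta = apply(nb[hit, , drop = FALSE], 1, max),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$block_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select the most variable genomic blocks
#'
#' Ranks blocks by the sample variance of their block beta over the given
#' samples and returns the top `n`; ties are broken by block id so the
#' selection is deterministic. Blocks with any missing value across the
#' samples are not eligible.
#'
#' @param bbeta Block-level beta matrix.
#' @param samples Sample ids to compute variance over (default all columns).
#' @param n Number of blocks to return (default 500).
#' @return Character vector of `n` block ids, ordered by decreasing variance.
#' @export
select_variable_blocks <- function(bbeta, samples = colnames(bbeta),
                                   n = 500) {
  stopifnot(all(samples %in% colnames(bbeta)))
  mat <- bbeta[, samples, drop = FALSE]
  complete <- rowSums(is.na(mat)) == 0
  mat <- mat[complete, , drop = FALSE]
  if (n > nrow(mat)) {
    stop("n (", n, ") exceeds the ", nrow(mat),
         " blocks with complete data")
  }
  m <- rowMeans(mat)
  v <- rowSums((mat - m)^2) / (ncol(mat) - 1)
  ord <- order(-v, rownames(mat))
  rownames(mat)[ord][seq_len(n)]
}

#' Hierarchical clustering of samples on block methylation
#'
#' Agglomerative clustering of samples using Euclidean distance between
#' their block beta vectors. When more blocks are supplied than
#' `element_cap`, a seeded uniform random subsample of `element_cap` blocks
#' is used, mirroring the element limit of classic heatmap clustering
#' stacks; the seed is recorded in the result. Blocks with missing values
#' among the clustered samples are dropped with a warning (Euclidean
#' distance is undefined on missing cells). Samples are put in a canonical
#' (sorted) order before distance computation so the tree does not depend
#' on column order.
#'
#' @param bbeta Block-level beta matrix.
#' @param block_ids Blocks to cluster on (default all rows).
#' @param samples Samples to cluster (default all columns).
#' @param element_cap Maximum number of blocks used (default 20000).
#' @param seed Seed for the subsample draw.
#' @param linkage `"complete"` (default), `"average"` or `"ward"`.
#' @param k Number of clusters for the reported cut (default 2).
#' @return An object of class `cluster_result`: list with `hclust` (the
#'   merge tree), `labels_at_k` (named cluster labels), `k`, `blocks_used`,
#'   `subsample_seed`, `linkage`.
#' @export
cluster_samples <- function(bbeta, block_ids = rownames(bbeta),
                            samples = colnames(bbeta), element_cap = 20000,
                            seed = 1,
                            linkage = c("complete", "average", "ward"),
                            k = 2) {
  linkage <- match.arg(linkage)
  if (length(samples) < 2) {
    stop("clustering requires at least 2 samples")
  }
  stopifnot(all(block_ids %in% rownames(bbeta)),
            all(samples %in% colnames(bbeta)))
  samples <- sort(samples)
  block_ids <- sort(unique(block_ids))
  mat <- bbeta[block_ids, samples, drop = FALSE]
  incomplete <- rowSums(is.na(mat)) > 0
  if (any(incomplete)) {
    warning(sum(incomplete), " block(s) with missing values dropped ",
            "before clustering")
    mat <- mat[!incomplete, , drop = FALSE]
  }
  if (nrow(mat) == 0) stop("no blocks with complete data to cluster on")
  if (nrow(mat) > element_cap) {
    keep <- with_seed(seed, sample.int(nrow(mat), element_cap))
    mat <- mat[sort(keep), , drop = FALSE]
  }
  hc <- stats::hclust(stats::dist(t(mat)),
                      method = if (linkage == "ward") "ward.D2" else linkage)
  labels <- stats::cutree(hc, k = k)
  structure(list(hclust = hc, labels_at_k = labels, k = k,
                 blocks_used = rownames(mat), subsample_seed = seed,
                 linkage = linkage),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("Hierarchical clustering of", length(x$labels_at_k), "samples on",
      length(x$blocks_used), "blocks\n")
  cat("linkage:", x$linkage, " cut at k =", x$k, "\n")
  print(table(cluster = x$labels_at_k))
  invisible(x)
}

#' Fraction of methylated reference CpG-island blocks in a sample
#'
#' Given a reference set of normally unmethylated CpG-island blocks
#' (see [normally_unmethylated_cgi_blocks()]), computes the fraction of
#' those blocks called `methylated` in the sample, out of the reference
#' blocks with a non-missing beta. This is the per-sample CpG-island
#' methylation load used to compare methylator phenotypes across tumors.
#'
#' @param bbeta Block-level beta matrix.
#' @param sample A single sample id.
#' @param reference_blocks Nonempty character vector of block ids.
#' @param material `"tissue"` or `"cell_line"` (picks the methylated
#'   threshold).
#' @return Fraction in `[0, 1]`.
#' @export
methylated_fraction <- function(bbeta, sample, reference_blocks,
                                material = "tissue") {
  if (length(reference_blocks) == 0) {
    stop("reference_blocks must be nonempty")
  }
  stopifnot(length(sample) == 1, sample %in% colnames(bbeta),
            all(reference_blocks %in% rownames(bbeta)))
  b <- bbeta[reference_blocks, sample]
  b <- b[!is.na(b)]
  if (length(b) == 0) {
    stop("all reference blocks are missing for sample ", sample)
  }
  mean(call_state(b, material) == "methylated")
}
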