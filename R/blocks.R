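#' Assemble CpG probes into genomic blocks
#'
#' Groups probes into genomic blocks keyed by
#' `(gene, tss_relation, cgi_relation, cgi_id)`, the annotation axes that
#' locate a probe relative to transcription start sites and CpG islands.
#' A probe annotated to several genes (a `";"`-separated `gene` field)
#' contributes to one block per gene; probes with no gene annotation are
#' grouped under a `NA` gene with the remaining key components. Block ids are
#' derived deterministically from the key, so assembly is idempotent and
#' independent of probe order.
#'
#' @param probes Probe records as returned by [load_manifest()].
#' @return A `data.frame` with one row per block: `block_id`, `gene`,
#'   `tss_relation`, `cgi_relation`, `cgi_id`, `n_probes`, and a list-column
#'   `probe_ids` of member probes, sorted by `block_id`.
#' @seealso [block_beta()]
#' @export
assemble_blocks <- function(probes) {
  if (nrow(probes) == 0) {
    return(data.frame(block_id = character(), gene = character(),
                      tss_relation = character(), cgi_relation = character(),
                      cgi_id = character(), n_probes = integer(),
                      probe_ids = I(list())))
  }
  # expand probe-gene pairs; NA gene kept as a single pair
  gene_lists <- strsplit(ifelse(is.na(probes$gene), "\01", probes$gene),
                         ";", fixed = TRUE)
  reps <- lengths(gene_lists)
  long <- data.frame(
    probe_id = rep(probes$probe_id, reps),
    gene = unlist(gene_lists, use.names = FALSE),
    tss_relation = rep(probes$tss_relation, reps),
    cgi_relation = rep(probes$cgi_relation, reps),
    cgi_id = rep(probes$cgi_id, reps),
    stringsAsFactors = FALSE
  )
  long$gene[long$gene == "\01"] <- NA_character_
  key <- block_key(long$gene, long$tss_relation, long$cgi_relation,
                   long$cgi_id)
  members <- split(long$probe_id, key)
  first <- long[!duplicated(key), , drop = FALSE]
  first <- first[order(block_key(first$gene, first$tss_relation,
                                 first$cgi_relation, first$cgi_id)), ,
                 drop = FALSE]
  out <- data.frame(
    block_id = names(members),
    gene = first$gene,
    tss_relation = first$tss_relation,
    cgi_relation = first$cgi_relation,
    cgi_id = first$cgi_id,
    n_probes = lengths(members),
    stringsAsFactors = FALSE
  )
  out$probe_ids <- I(unname(members))
  rownames(out) <- NULL
  out
}

block_key <- function(gene, tss_relation, cgi_relation, cgi_id) {
  paste(ifelse(is.na(gene), ".", gene), tss_relation, cgi_relation,
        ifelse(is.na(cgi_id), ".", cgi_id), sep = "|")
}

#' Summarize a probe-level beta matrix at the block level
#'
#' The methylation level of a genomic block in a sample is the arithmetic
#' mean of the non-missing beta values of its member probes; averaging
#' isolates densely methylated CpG islands, the signal relevant to
#' methylation-silencing. A block's value is missing only when all of its
#' probes are missing in that sample.
#'
#' @param beta Numeric matrix of beta values in `[0, 1]`, probes in rows
#'   (rownames = probe ids), samples in columns.
#' @param blocks Blocks from [assemble_blocks()].
#' @return Numeric matrix of block-level mean betas, block ids in rows,
#'   samples in columns.
#' @export
block_beta <- function(beta, blocks) {
  stopifnot(is.matrix(beta), !is.null(rownames(beta)))
  if (!all(is.na(beta))) {
    rng <- range(beta, na.rm = TRUE)
    if (rng[1] < 0 || rng[2] > 1) {
      stop("beta values must lie in [0, 1]")
    }
  }
  idx <- rep(seq_len(nrow(blocks)), lengths(blocks$probe_ids))
  pid <- unlist(blocks$probe_ids, use.names = FALSE)
  present <- pid %in% rownames(beta)
  absent_blocks <- setdiff(seq_len(nrow(blocks)), idx[present])
  if (length(absent_blocks) > 0) {
    warning(length(absent_blocks),
            " block(s) have no probes in the beta matrix; values set missing")
  }
  sub <- beta[pid[present], , drop = FALSE]
  grp <- idx[present]
  filled <- sub
  filled[is.na(filled)] <- 0
  sums <- rowsum(filled, grp)
  counts <- rowsum((!is.na(sub)) * 1L, grp)
  means <- sums / counts
  means[counts == 0] <- NA_real_
  out <- matrix(NA_real_, nrow = nrow(blocks), ncol = ncol(beta),
                dimnames = list(blocks$block_id, colnames(beta)))
  out[as.integer(rownames(sums)), ] <- means
  out
}
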