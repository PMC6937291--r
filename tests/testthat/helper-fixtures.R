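# Small in-code fixtures shared across test files.

# A probe-record data.frame from parallel vectors, with manifest defaults.
make_probes <- function(probe_id, gene, tss_relation = "TSS200",
                        cgi_relation = "Island", cgi_id = "CGI_1",
                        chrom = "chr1", pos = seq_along(probe_id) * 100) {
  n <- length(probe_id)
  gene <- rep_len(gene, n)
  tss_relation <- rep_len(tss_relation, n)
  cgi_relation <- rep_len(cgi_relation, n)
  cgi_id <- rep_len(cgi_id, n)
  chrom <- rep_len(chrom, n)
  data.frame(probe_id = probe_id, chrom = chrom, pos = pos, gene = gene,
             tss_relation = tss_relation, cgi_relation = cgi_relation,
             cgi_id = ifelse(cgi_relation %in% c("Island", "Shore", "Shelf"),
                             cgi_id, NA_character_),
             stringsAsFactors = FALSE)
}

# A block-level beta matrix from a named list of per-block sample vectors.
make_bbeta <- function(rows, sample_ids) {
  mat <- do.call(rbind, rows)
  dimnames(mat) <- list(names(rows), sample_ids)
  mat
}

# Per-cell loop oracle for block_beta: independent of the rowsum path.
block_beta_oracle <- function(beta, blocks) {
  out <- matrix(NA_real_, nrow(blocks), ncol(beta),
                dimnames = list(blocks$block_id, colnames(beta)))
  for (i in seq_len(nrow(blocks))) {
    pids <- intersect(blocks$probe_ids[[i]], rownames(beta))
    for (j in seq_len(ncol(beta))) {
      vals <- beta[pids, j]
      vals <- vals[!is.na(vals)]
      if (length(vals) > 0) out[i, j] <- sum(vals) / length(vals)
    }
  }
  out
}

# A random probe-level beta matrix with optional missingness.
random_beta <- function(n_probes, n_samples, na_frac = 0) {
  mat <- matrix(stats::runif(n_probes * n_samples), n_probes, n_samples,
                dimnames = list(sprintf("cg%05d", seq_len(n_probes)),
                                sprintf("S%02d", seq_len(n_samples))))
  if (na_frac > 0) {
    mat[sample(length(mat), round(na_frac * length(mat)))] <- NA
  }
  mat
}
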