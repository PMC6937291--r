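#' Percentage of methylated reference (PMR)
#'
#' Quantifies DNA methylation from quantitative methylation-specific PCR
#' molecule counts:
#' `PMR = ((sample meth / sample Alu) / (reference meth / reference Alu)) * 100`,
#' where the reference is fully (SssI-) methylated DNA and Alu repeat counts
#' normalize DNA input — Alu copy number is little affected by
#' cancer-associated aneuploidy, unlike single-copy genes. PMR above 100 is
#' possible with assay noise and is reported with a warning, not clamped.
#'
#' @param meth,alu Methylated-molecule and Alu-repeat counts of the sample
#'   (vectors are allowed and recycled against the reference).
#' @param ref_meth,ref_alu Counts of the fully methylated reference for the
#'   same target CpG island.
#' @return Numeric PMR value(s), in percent.
#' @examples
#' compute_pmr(100, 1000, 200, 1000) # 50
#' @export
compute_pmr <- function(meth, alu, ref_meth, ref_alu) {
  if (any(alu <= 0) || any(ref_alu <= 0)) {
    stop("Alu molecule counts must be positive")
  }
  if (any(ref_meth <= 0)) {
    stop("fully methylated reference has no methylated molecules; ",
         "PMR is undefined")
  }
  if (any(meth < 0)) {
    stop("methylated-molecule counts must be nonnegative")
  }
  pmr <- ((meth / alu) / (ref_meth / ref_alu)) * 100
  if (any(pmr > 100)) {
    warning("PMR above 100 for ", sum(pmr > 100),
            " measurement(s); reported unclamped")
  }
  pmr
}

#' Compute PMR for a table of qMSP measurements
#'
#' Takes a measurement table (columns `sample_id`, `target_id`,
#' `meth_molecules`, `alu_molecules`, `is_reference`) with one row per well.
#' Replicate wells of the same sample and target are averaged on the
#' molecule-count scale before PMR computation. Each target must have
#' reference (fully methylated DNA) rows.
#'
#' @param measurements `data.frame` of qMSP wells (see [read_qmsp()]).
#' @return `data.frame` with columns `sample_id`, `target_id`, `pmr`.
#' @export
pmr_table <- function(measurements) {
  required <- c("sample_id", "target_id", "meth_molecules", "alu_molecules",
                "is_reference")
  missing_cols <- setdiff(required, names(measurements))
  if (length(missing_cols) > 0) {
    stop("measurement table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  m <- measurements
  m$is_reference <- as.logical(m$is_reference)
  agg <- stats::aggregate(cbind(meth_molecules, alu_molecules) ~
                            sample_id + target_id + is_reference,
                          data = m, FUN = mean)
  refs <- agg[agg$is_reference, , drop = FALSE]
  smp <- agg[!agg$is_reference, , drop = FALSE]
  no_ref <- setdiff(unique(smp$target_id), refs$target_id)
  if (length(no_ref) > 0) {
    stop("no fully methylated reference for target(s): ",
         paste(no_ref, collapse = ", "))
  }
  ref_idx <- match(smp$target_id, refs$target_id)
  out <- data.frame(
    sample_id = smp$sample_id,
    target_id = smp$target_id,
    pmr = compute_pmr(smp$meth_molecules, smp$alu_molecules,
                      refs$meth_molecules[ref_idx],
                      refs$alu_molecules[ref_idx]),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$target_id, out$sample_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a qMSP molecule-count table from CSV
#'
#' @param path CSV with columns `sample_id`, `target_id`, `meth_molecules`,
#'   `alu_molecules`, `is_reference` (logical or 0/1).
#' @return `data.frame` of measurements.
#' @export
read_qmsp <- function(path) {
  if (!file.exists(path)) {
    stop("qMSP file not found: ", path)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "target_id", "meth_molecules", "alu_molecules",
                "is_reference")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("qMSP file missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df$is_reference <- as.logical(df$is_reference)
  df
}
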