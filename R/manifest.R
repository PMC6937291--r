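#' Recognized TSS-relative probe categories
#'
#' Annotation levels for the position of a CpG probe relative to the nearest
#' transcription start site, as used on Infinium-style manifests.
#' @export
TSS_RELATIONS <- c("TSS200", "TSS1500", "UTR5", "FirstExon", "Body", "UTR3",
                   "Intergenic")

#' Recognized CpG-island relation categories
#'
#' Position of a probe relative to a CpG island: within the island, in the
#' flanking shores/shelves, or in the open sea. North/south directionality is
#' collapsed (it plays no role in block assembly).
#' @export
CGI_RELATIONS <- c("Island", "Shore", "Shelf", "OpenSea")

AUTOSOMES <- paste0("chr", 1:22)

#' Load and validate a probe-annotation manifest
#'
#' Reads a CSV manifest of CpG probes (columns `probe_id`, `chrom`, `pos`,
#' `gene`, `tss_relation`, `cgi_relation`, `cgi_id`) and returns validated
#' probe records. Probes on non-autosomal chromosomes are dropped, with the
#' count reported via a message, so that downstream analyses operate on
#' autosomal CpG sites only. The `gene` column may hold several
#' `";"`-separated gene symbols, or be empty for unannotated probes.
#'
#' @param path Path to the manifest CSV.
#' @param autosomes_only Drop probes outside chr1-chr22 (default `TRUE`).
#' @return A `data.frame` of probe records with columns `probe_id`, `chrom`,
#'   `pos`, `gene` (`NA` when unannotated), `tss_relation`, `cgi_relation`,
#'   `cgi_id` (`NA` for `OpenSea`/`Intergenic` context).
#' @seealso [assemble_blocks()]
#' @export
load_manifest <- function(path, autosomes_only = TRUE) {
  if (!file.exists(path)) {
    stop("manifest file not found: ", path)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  validate_manifest(df, autosomes_only = autosomes_only)
}

#' Validate probe records held in a data frame
#'
#' @param df Data frame with the manifest columns (see [load_manifest()]).
#' @param autosomes_only Drop non-autosomal probes (default `TRUE`).
#' @return Validated probe records (see [load_manifest()]).
#' @export
validate_manifest <- function(df, autosomes_only = TRUE) {
  required <- c("probe_id", "chrom", "pos", "gene", "tss_relation",
                "cgi_relation", "cgi_id")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("manifest is missing required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- df[required]
  df$pos <- suppressWarnings(as.integer(df$pos))
  df$gene[!is.na(df$gene) & df$gene == ""] <- NA_character_
  df$cgi_id[!is.na(df$cgi_id) & df$cgi_id == ""] <- NA_character_

  if (anyNA(df$pos) || any(df$pos < 1)) {
    stop("manifest positions must be integers >= 1 (1-based coordinates)")
  }
  dup <- duplicated(df$probe_id)
  if (any(dup)) {
    stop("duplicate probe_id in manifest: ",
         paste(unique(df$probe_id[dup]), collapse = ", "))
  }
  bad_tss <- setdiff(unique(df$tss_relation), TSS_RELATIONS)
  if (length(bad_tss) > 0) {
    stop("unknown tss_relation label(s): ", paste(bad_tss, collapse = ", "))
  }
  bad_cgi <- setdiff(unique(df$cgi_relation), CGI_RELATIONS)
  if (length(bad_cgi) > 0) {
    stop("unknown cgi_relation label(s): ", paste(bad_cgi, collapse = ", "))
  }
  # cgi_id must be present iff the probe has an island/shore/shelf context
  needs_id <- df$cgi_relation %in% c("Island", "Shore", "Shelf")
  if (any(needs_id & is.na(df$cgi_id))) {
    stop("cgi_id missing for Island/Shore/Shelf probe(s)")
  }
  if (any(!needs_id & !is.na(df$cgi_id))) {
    stop("cgi_id present for OpenSea probe(s); expected empty")
  }

  if (autosomes_only) {
    drop <- !(df$chrom %in% AUTOSOMES)
    if (any(drop)) {
      message(sum(drop), " non-autosomal probe(s) dropped")
      df <- df[!drop, , drop = FALSE]
    }
  }
  rownames(df) <- NULL
  df
}

#' Write a probe manifest to CSV
#'
#' Inverse of [load_manifest()]; `NA` genes and CGI ids are written as empty
#' cells.
#'
#' @param probes Probe records as returned by [load_manifest()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(probes, path) {
  utils::write.csv(probes, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}
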