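#' Read a probe-by-sample beta matrix from TSV
#'
#' First column `probe_id`, remaining columns one per sample; empty cells are
#' missing values.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix, probes in rows, samples in columns.
#' @export
read_beta_matrix <- function(path) {
  read_value_matrix(path, id_col = "probe_id", lo = 0, hi = 1)
}

#' Read a probe- or gene-level expression matrix from TSV
#'
#' First column holds probe (or gene) identifiers, remaining columns samples.
#' Values must be nonnegative signal intensities.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix of nonnegative signals.
#' @export
read_expression_matrix <- function(path) {
  read_value_matrix(path, id_col = NULL, lo = 0, hi = Inf)
}

read_value_matrix <- function(path, id_col = NULL, lo = -Inf, hi = Inf) {
  if (!file.exists(path)) {
    stop("matrix file not found: ", path)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2) {
    stop("matrix file needs an id column plus at least one sample: ", path)
  }
  if (!is.null(id_col) && names(df)[1] != id_col) {
    stop("first column of ", path, " must be '", id_col, "'")
  }
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop("duplicate row identifiers in ", path)
  }
  mat <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  rng <- range(mat, na.rm = TRUE)
  if (rng[1] < lo || rng[2] > hi) {
    stop("values in ", path, " outside [", lo, ", ", hi, "]")
  }
  mat
}

#' Write a numeric matrix to TSV with an id column
#'
#' @param mat Numeric matrix with rownames.
#' @param path Output path.
#' @param id_col Name for the identifier column.
#' @return `path`, invisibly.
#' @export
write_value_matrix <- function(mat, path, id_col = "probe_id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a sample sheet from TSV
#'
#' Columns: `sample_id`, `material` (`tissue`/`cell_line`), `group`
#' (`tumor_primary`, `tumor_metastasis`, `normal`, `mock`, `treated`),
#' `patient_id` (may be empty).
#'
#' @param path Path to the TSV file.
#' @return Validated `data.frame`.
#' @export
read_sample_sheet <- function(path) {
  if (!file.exists(path)) {
    stop("sample sheet not found: ", path)
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  validate_sample_sheet(df)
}

SAMPLE_GROUPS <- c("tumor_primary", "tumor_metastasis", "normal", "mock",
                   "treated")

validate_sample_sheet <- function(df) {
  required <- c("sample_id", "material", "group", "patient_id")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("sample sheet missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- df[required]
  if (anyDuplicated(df$sample_id)) {
    stop("duplicate sample_id in sample sheet")
  }
  bad_mat <- setdiff(unique(df$material), c("tissue", "cell_line"))
  if (length(bad_mat) > 0) {
    stop("unknown material label(s): ", paste(bad_mat, collapse = ", "))
  }
  bad_grp <- setdiff(unique(df$group), SAMPLE_GROUPS)
  if (length(bad_grp) > 0) {
    stop("unknown group label(s): ", paste(bad_grp, collapse = ", "))
  }
  df$patient_id[!is.na(df$patient_id) & df$patient_id == ""] <- NA_character_
  rownames(df) <- NULL
  df
}

#' Write a sample sheet to TSV
#' @param sheet Sample sheet `data.frame` (see [read_sample_sheet()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a probe-to-gene mapping from CSV
#'
#' @param path CSV with columns `probe_id`, `gene`.
#' @return `data.frame` with columns `probe_id`, `gene`.
#' @export
read_probe_gene_map <- function(path) {
  if (!file.exists(path)) {
    stop("probe-gene map not found: ", path)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!all(c("probe_id", "gene") %in% names(df))) {
    stop("probe-gene map must have columns probe_id, gene")
  }
  df[c("probe_id", "gene")]
}
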