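#' Aberrant promoter-methylation sets for a primary-metastasis pair
#'
#' For a matched primary tumor and metastasis, computes the per-lesion sets
#' of aberrantly methylated blocks within an evaluated universe: blocks with
#' beta >= `meth_threshold` (tissue methylated bound, 0.40) in the lesion.
#' The universe should come from upstream analysis (TSS200 CpG-island
#' blocks unmethylated in normals for genes expressed in the presumed cells
#' of origin); when `normals` is supplied, the universe is additionally
#' filtered to blocks unmethylated in every normal. Blocks with a missing
#' beta in either lesion are removed from the universe.
#'
#' @param bbeta Block-level beta matrix.
#' @param primary,metastasis Sample ids of the matched pair.
#' @param universe Character vector of evaluated block ids.
#' @param normals Optional normal sample ids for re-filtering the universe.
#' @param config [aberrant_config()] supplying the thresholds.
#' @param patient_id Optional patient identifier carried into the result.
#' @return Object of class `methylation_pair`: list with `patient_id`,
#'   `primary_aberrant`, `met_aberrant`, `universe`.
#' @export
pair_sets <- function(bbeta, primary, metastasis, universe, normals = NULL,
                      config = aberrant_config(), patient_id = NA_character_) {
  missing_samples <- setdiff(c(primary, metastasis), colnames(bbeta))
  if (length(missing_samples) > 0) {
    stop("sample(s) absent from block beta matrix: ",
         paste(missing_samples, collapse = ", "))
  }
  stopifnot(length(primary) == 1, length(metastasis) == 1,
            all(universe %in% rownames(bbeta)))
  universe <- sort(unique(universe))
  if (!is.null(normals)) {
    nb <- bbeta[universe, normals, drop = FALSE]
    keep <- rowSums(nb < config$unmeth_threshold) == length(normals)
    keep[is.na(keep)] <- FALSE
    universe <- universe[keep]
  }
  bp <- bbeta[universe, primary]
  bm <- bbeta[universe, metastasis]
  evaluable <- !is.na(bp) & !is.na(bm)
  universe <- universe[evaluable]
  bp <- bp[evaluable]
  bm <- bm[evaluable]
  structure(list(
    patient_id = patient_id,
    primary_aberrant = universe[bp >= config$meth_threshold],
    met_aberrant = universe[bm >= config$meth_threshold],
    universe = universe
  ), class = "methylation_pair")
}

#' Construct a methylation pair from explicit sets
#'
#' Lower-level constructor used by the simulator and for set-based analyses
#' where beta values are not available.
#'
#' @param primary_aberrant,met_aberrant Character vectors of block ids.
#' @param universe Evaluated block set (must contain both aberrant sets).
#' @param patient_id Optional patient identifier.
#' @return Object of class `methylation_pair`.
#' @export
methylation_pair <- function(primary_aberrant, met_aberrant, universe,
                             patient_id = NA_character_) {
  primary_aberrant <- sort(unique(primary_aberrant))
  met_aberrant <- sort(unique(met_aberrant))
  universe <- sort(unique(universe))
  if (!all(c(primary_aberrant, met_aberrant) %in% universe)) {
    stop("aberrant sets must be subsets of the universe")
  }
  structure(list(patient_id = patient_id,
                 primary_aberrant = primary_aberrant,
                 met_aberrant = met_aberrant,
                 universe = universe),
            class = "methylation_pair")
}

#' Classify clonal versus parallel evolution of a metastasis
#'
#' Compares the aberrant promoter-methylation sets of a primary tumor (P)
#' and its metastasis (M). When the metastasis retains the primary's
#' aberrant methylation — shared fraction `|P ∩ M| / |P|` at or above
#' `shared_fraction_min` — the pair shows clonal evolution: the metastasis
#' descends from the dominant primary clone, with or without additional
#' private events. When only a fraction of the primary's methylation is
#' shared and the metastasis carries private methylation of its own, the
#' two lesions diverged from a common ancestor: parallel evolution. A pair
#' with low shared fraction but no metastasis-private methylation does not
#' fit either description; it is reported as clonal with a warning
#' (methylation regression edge case).
#'
#' @param pair A `methylation_pair` (from [pair_sets()] or
#'   [methylation_pair()]); its primary set must be nonempty.
#' @param shared_fraction_min Threshold on the shared fraction of the
#'   primary set (default 0.75).
#' @return Object of class `evolution_call`: list with `patient_id`,
#'   `pattern` (`"clonal"` or `"parallel"`), `shared`, `primary_private`,
#'   `met_private`, `shared_fraction_of_primary`, `edge_case`.
#' @export
classify_evolution <- function(pair, shared_fraction_min = 0.75) {
  stopifnot(inherits(pair, "methylation_pair"))
  p <- pair$primary_aberrant
  m <- pair$met_aberrant
  if (length(p) == 0) {
    stop("primary aberrant set is empty; classification undefined")
  }
  shared <- length(intersect(p, m))
  frac <- shared / length(p)
  met_private <- length(setdiff(m, p))
  edge <- FALSE
  if (frac >= shared_fraction_min) {
    pattern <- "clonal"
  } else if (met_private > 0) {
    pattern <- "parallel"
  } else {
    pattern <- "clonal"
    edge <- TRUE
    warning("shared fraction ", signif(frac, 3), " below threshold but no ",
            "metastasis-private methylation; reported as clonal ",
            "(methylation regression edge case)")
  }
  structure(list(
    patient_id = pair$patient_id,
    pattern = pattern,
    shared = shared,
    primary_private = length(p) - shared,
    met_private = met_private,
    shared_fraction_of_primary = frac,
    edge_case = edge
  ), class = "evolution_call")
}

#' @export
print.evolution_call <- function(x, ...) {
  cat("Evolution call",
      if (!is.na(x$patient_id)) paste0("(patient ", x$patient_id, ")"),
      ":", x$pattern, "\n")
  cat("  shared:", x$shared, " primary-private:", x$primary_private,
      " metastasis-private:", x$met_private, "\n")
  cat("  shared fraction of primary:",
      signif(x$shared_fraction_of_primary, 3), "\n")
  invisible(x)
}
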