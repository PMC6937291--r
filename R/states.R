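#' Methylation state labels
#' @export
METHYLATION_STATES <- c("unmethylated", "partial", "methylated")

#' Call three-state methylation status from a beta value
#'
#' Classifies block (or probe) beta values into `unmethylated`, `partial`
#' (partially methylated) or `methylated`, using material-specific intervals:
#' for tissues, unmethylated `[0, 0.2)`, partial `[0.2, 0.4)`, methylated
#' `[0.4, 1]`; for cancer cell lines the partial interval widens to
#' `[0.2, 0.8)` and methylated is `[0.8, 1]`, reflecting the near-clonal
#' methylation patterns of cell lines versus the stromal admixture of
#' tissues. Intervals are half-open at the lower bound with the methylated
#' class inclusive at its threshold (beta >= 0.4, resp. >= 0.8).
#'
#' @param beta Numeric vector of beta values in `[0, 1]`; `NA` propagates.
#' @param material `"tissue"` or `"cell_line"`; recycled along `beta`.
#' @return Factor with levels `unmethylated`, `partial`, `methylated`.
#' @examples
#' call_state(c(0.45, 0.45), c("tissue", "cell_line"))
#' @export
call_state <- function(beta, material = "tissue") {
  if (!all(material %in% c("tissue", "cell_line"))) {
    stop("material must be 'tissue' or 'cell_line'")
  }
  ok <- is.na(beta) | (beta >= 0 & beta <= 1)
  if (!all(ok)) {
    stop("beta values must lie in [0, 1]")
  }
  material <- rep_len(material, length(beta))
  meth_thr <- ifelse(material == "tissue", 0.4, 0.8)
  state <- ifelse(beta < 0.2, "unmethylated",
                  ifelse(beta < meth_thr, "partial", "methylated"))
  factor(state, levels = METHYLATION_STATES)
}

#' State thresholds for a material class
#'
#' @param material `"tissue"` or `"cell_line"`.
#' @return Named numeric vector with `unmeth` (upper bound of the
#'   unmethylated class) and `meth` (lower bound of the methylated class).
#' @export
state_thresholds <- function(material = c("tissue", "cell_line")) {
  material <- match.arg(material)
  c(unmeth = 0.2, meth = if (material == "tissue") 0.4 else 0.8)
}
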