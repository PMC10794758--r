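## The sixteen named feature combinations.
##
## Five feature families: BP (period-3 peak + SNR, 2 columns), DP and TP
## (3 energy columns each), DC and TC (up to 15 PCA components each).
## Combinations cap the assembled width at 15, picking top-variance PCs
## when a family is truncated. Naming note: the letters in the published
## combination names do not always match their own family lists; this
## registry follows the count arithmetic and the abbreviations used in the
## metric reports (DPDC, TPTC, DCTC, DPTPDCTC), the internally consistent
## reading. For DPTPDCTC the printed split "3+4+3+5" lists families in the
## order TP, TC, DP, DC; in canonical family order that is DP:3, TP:3,
## DC:5, TC:4.

FAMILY_CAPACITY <- c(BP = 2L, DP = 3L, TP = 3L, DC = 15L, TC = 15L)

COMBO_TABLE <- list(
  DP       = c(DP = 3L),
  TP       = c(TP = 3L),
  DPTP     = c(DP = 3L, TP = 3L),
  DC       = c(DC = 15L),
  TC       = c(TC = 15L),
  BP       = c(BP = 2L),
  BPDP     = c(BP = 2L, DP = 3L),
  BPTP     = c(BP = 2L, TP = 3L),
  BPDPTP   = c(BP = 2L, DP = 3L, TP = 3L),
  BPDC     = c(BP = 2L, DC = 13L),
  BPTC     = c(BP = 2L, TC = 13L),
  BPDCTC   = c(BP = 2L, DC = 7L, TC = 6L),
  DPDC     = c(DP = 3L, DC = 12L),
  TPTC     = c(TP = 3L, TC = 12L),
  DCTC     = c(DC = 8L, TC = 7L),
  DPTPDCTC = c(DP = 3L, TP = 3L, DC = 5L, TC = 4L)
)

## Column names each family contributes, in selection order. DC/TC columns
## are PCA scores already sorted by decreasing explained variance, so the
## first n are the top-variance components.
family_columns <- function(family, n) {
  switch(family,
    BP = c("bp_peak", "bp_snr")[seq_len(n)],
    DP = paste0("dp_", ENERGY_COLS)[seq_len(n)],
    TP = paste0("tp_", ENERGY_COLS)[seq_len(n)],
    DC = paste0("dc_pc", seq_len(n)),
    TC = paste0("tc_pc", seq_len(n)),
    stop("unknown feature family: ", family)
  )
}

#' The feature-combination registry
#'
#' @return named list of `"combo_spec"` objects, one per combination.
#' @export
combo_registry <- function() {
  lapply(stats::setNames(names(COMBO_TABLE), names(COMBO_TABLE)), combo_spec)
}

#' Look up one feature combination
#'
#' @param name one of the 16 combination names (e.g. `"BPDC"`).
#' @return object of class `"combo_spec"`: list with `name`, `parts`
#'   (named integer vector, family -> number of columns selected) and
#'   `total`.
#' @export
combo_spec <- function(name) {
  if (!name %in% names(COMBO_TABLE))
    stop("unknown combination '", name, "'; valid names: ",
         paste(names(COMBO_TABLE), collapse = ", "))
  parts <- COMBO_TABLE[[name]]
  stopifnot(all(parts <= FAMILY_CAPACITY[names(parts)]))
  structure(list(name = name, parts = parts, total = sum(parts)),
            class = "combo_spec")
}

#' @export
print.combo_spec <- function(x, ...) {
  cat(x$name, ": ", paste(sprintf("%s:%d", names(x$parts), x$parts),
                          collapse = " + "),
      " = ", x$total, " columns\n", sep = "")
  invisible(x)
}

#' Assemble a model-input matrix for one combination
#'
#' Concatenates the selected columns of each family in the combination's
#' order, aligning rows by sequence id. Column provenance (feature name ->
#' family) is attached as the `"provenance"` attribute.
#'
#' @param combo a `"combo_spec"` or a combination name.
#' @param store named list of per-family feature-matrix data.frames
#'   (`BP`, `DP`, `TP`, `DC`, `TC` as required by the combo; each with
#'   `id` and `label` columns).
#' @return feature-matrix data.frame: `id`, `label`, then the combined
#'   feature columns.
#' @export
assemble_features <- function(combo, store) {
  if (is.character(combo)) combo <- combo_spec(combo)
  stopifnot(inherits(combo, "combo_spec"))
  fams <- names(combo$parts)
  missing <- setdiff(fams, names(store))
  if (length(missing))
    stop("feature store lacks famil(ies): ", paste(missing, collapse = ", "))
  mats <- align_by_id(store[fams])
  out <- mats[[1]][, c("id", "label"), drop = FALSE]
  prov <- character(0)
  for (fam in fams) {
    cols <- family_columns(fam, combo$parts[[fam]])
    absent <- setdiff(cols, names(mats[[fam]]))
    if (length(absent))
      stop("family ", fam, " lacks column(s): ", paste(absent, collapse = ", "))
    out <- cbind(out, mats[[fam]][, cols, drop = FALSE])
    prov <- c(prov, stats::setNames(rep(fam, length(cols)), cols))
  }
  stopifnot(ncol(out) - 2L == combo$total)
  attr(out, "provenance") <- prov
  out
}
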