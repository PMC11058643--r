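#' Drug-likeness window filter for pretraining corpora
#'
#' Retains molecules with molecular weight and logP inside the windows used
#' to assemble ZINC-style drug-like pretraining sets: 200 <= MolWt <= 500
#' g/mol and 0 <= logP <= 5, bounds inclusive. The filter is pure: the
#' result is an order-preserving subset of the input rows.
#'
#' @param df Data frame with numeric `MolWt` and `logP` columns.
#' @param molwt_range,logp_range Numeric length-2 inclusive bounds.
#' @return The retained rows of `df`.
#' @export
filter_pretraining <- function(df, molwt_range = c(200, 500),
                               logp_range = c(0, 5)) {
  stopifnot(is.data.frame(df), all(c("MolWt", "logP") %in% names(df)))
  keep <- df$MolWt >= molwt_range[1] & df$MolWt <= molwt_range[2] &
    df$logP >= logp_range[1] & df$logP <= logp_range[2]
  keep[is.na(keep)] <- FALSE
  df[keep, , drop = FALSE]
}

#' Bioactivity filter for fine-tuning sets
#'
#' Retains records whose pIC50 or pEC50 (whichever is available) exceeds the
#' activity threshold — strictly greater than 6 by default, the conventional
#' 1 uM potency cutoff on the -log10 molar scale. Records with no activity
#' value at all are dropped with a warning. Duplicate molecules are removed
#' after canonicalization, keeping the first occurrence.
#'
#' @param df Data frame with a `smiles` column and at least one of `pIC50`,
#'   `pEC50` (numeric, `NA` allowed).
#' @param threshold Activity cutoff; retained iff any value `> threshold`.
#' @return Retained rows, with a `canonical` column added, deduplicated.
#' @export
filter_actives <- function(df, threshold = 6) {
  stopifnot(is.data.frame(df), "smiles" %in% names(df))
  acts <- intersect(c("pIC50", "pEC50"), names(df))
  if (length(acts) == 0L) stop("need a pIC50 or pEC50 column")
  amat <- as.matrix(df[, acts, drop = FALSE])
  has_value <- rowSums(!is.na(amat)) > 0L
  if (any(!has_value)) {
    warning(sprintf("%d record(s) with no activity value excluded",
                    sum(!has_value)))
  }
  active <- has_value & apply(amat, 1L, function(r) any(r > threshold, na.rm = TRUE))
  out <- df[active, , drop = FALSE]
  if (nrow(out) == 0L) return(cbind(out, canonical = character(0)))
  out$canonical <- canonicalize(out$smiles)
  out <- out[!is.na(out$canonical), , drop = FALSE]
  out[!duplicated(out$canonical), , drop = FALSE]
}
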