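# Property standardization. The networks see z-scored property values; the
# (mean, sd) pair per property is estimated on the pretraining corpus,
# stored in the checkpoint, and reused unchanged during fine-tuning and
# generation so user-facing targets in natural units map consistently into
# model space.

#' Estimate standardization statistics for a property matrix
#'
#' @param y Numeric matrix (molecules x properties) with column names.
#' @return A `prop_stats` object: list of per-property `mean` and `sd`.
#' @export
property_stats <- function(y) {
  y <- as.matrix(y)
  stopifnot(!is.null(colnames(y)))
  sds <- apply(y, 2L, stats::sd)
  if (any(!is.finite(sds)) || any(sds <= 0)) {
    stop("each property needs a finite, positive standard deviation")
  }
  structure(list(mean = colMeans(y), sd = sds, names = colnames(y)),
            class = "prop_stats")
}

#' Standardize or de-standardize property values
#'
#' `standardize_properties()` z-scores each column with the stored stats and
#' tags the result; `destandardize_properties()` inverts it exactly (to
#' within floating-point round-off). Several model entry points require the
#' standardized tag and refuse raw-unit input.
#'
#' @param y Numeric matrix (molecules x properties), columns named as in
#'   `stats$names`.
#' @param stats A `prop_stats` object.
#' @return Matrix of the same shape; standardized matrices carry
#'   `attr(, "standardized") == TRUE`.
#' @export
standardize_properties <- function(y, stats) {
  stopifnot(inherits(stats, "prop_stats"))
  y <- as.matrix(y)
  if (is.null(colnames(y))) colnames(y) <- stats$names
  stopifnot(identical(colnames(y), stats$names))
  out <- sweep(sweep(y, 2L, stats$mean, "-"), 2L, stats$sd, "/")
  attr(out, "standardized") <- TRUE
  out
}

#' @rdname standardize_properties
#' @export
destandardize_properties <- function(y, stats) {
  stopifnot(inherits(stats, "prop_stats"))
  y <- as.matrix(y)
  out <- sweep(sweep(y, 2L, stats$sd, "*"), 2L, stats$mean, "+")
  attr(out, "standardized") <- NULL
  out
}

is_standardized <- function(y) isTRUE(attr(y, "standardized"))
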