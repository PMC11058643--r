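#' Validity of a generated set
#'
#' Fraction of generation attempts that yielded a chemically valid molecule:
#' the SMILES parses and sanitizes under the toolkit, and the sequence
#' terminated with the end token within the step budget. The denominator is
#' the total number of attempts.
#'
#' @param raw Character vector of raw generated SMILES (all attempts), or a
#'   library data frame from [generate_library()] (its `valid` column is
#'   used directly).
#' @param terminated Logical vector flagging terminated sequences (default
#'   all `TRUE`); ignored for a library data frame.
#' @return Fraction in \[0, 1\].
#' @export
validity <- function(raw, terminated = NULL) {
  if (is.data.frame(raw)) {
    if (nrow(raw) == 0L) stop("empty generated set")
    return(mean(raw$valid))
  }
  if (length(raw) == 0L) stop("empty generated set")
  if (is.null(terminated)) terminated <- rep(TRUE, length(raw))
  ok <- nzchar(raw) & terminated
  ok[ok] <- !is.na(canonicalize(raw[ok]))
  mean(ok)
}

#' Uniqueness of the valid molecules
#'
#' Number of distinct canonical forms divided by the number of valid
#' molecules. Low uniqueness signals a model that repeats itself.
#'
#' @param canonical Character vector of canonical SMILES of the valid
#'   molecules, or a library data frame (valid rows are used).
#' @return Fraction in \(0, 1\].
#' @export
uniqueness <- function(canonical) {
  canonical <- valid_canonical(canonical)
  if (length(canonical) == 0L) stop("empty valid set")
  length(unique(canonical)) / length(canonical)
}

#' Novelty of the valid molecules relative to the training set
#'
#' Default (`variant = "fraction_new"`): the fraction of distinct valid
#' molecules that do not occur in the training set,
#' `|set(V) \ X| / |set(V)|`. The alternative `variant = "overlap"`
#' computes `|set(V) intersect X| / |V|`, i.e. the share of valid outputs
#' whose distinct forms also occur in training; it is retained for audit
#' because both definitions circulate. Membership is tested by canonical
#' SMILES string equality, so the training set must be canonicalized with
#' the same settings.
#'
#' @param canonical Canonical SMILES of the valid generated molecules, or a
#'   library data frame.
#' @param training Character vector of canonical training SMILES.
#' @param variant `"fraction_new"` (default) or `"overlap"`.
#' @return Fraction in \[0, 1\].
#' @export
novelty <- function(canonical, training,
                    variant = c("fraction_new", "overlap")) {
  variant <- match.arg(variant)
  canonical <- valid_canonical(canonical)
  if (length(canonical) == 0L || length(training) == 0L) {
    stop("empty generated or training set")
  }
  distinct <- unique(canonical)
  if (variant == "fraction_new") {
    length(setdiff(distinct, training)) / length(distinct)
  } else {
    length(intersect(distinct, training)) / length(canonical)
  }
}

valid_canonical <- function(x) {
  if (is.data.frame(x)) x$canonical_smiles[x$valid] else x
}

#' Property-distribution report for a generated set against a reference
#'
#' Per-property summary statistics (mean, sd, quartiles) for both sets and
#' their mean differences (generated minus reference).
#'
#' @param generated,reference Data frames with numeric property columns
#'   (e.g. library data frames or [compute_properties()] output).
#' @param properties Property columns to summarize.
#' @return List with `summary` (long data frame: set, property, mean, sd,
#'   q25, median, q75, n) and `mean_diff` (named numeric).
#' @export
property_report <- function(generated, reference,
                            properties = c("logP", "MolWt", "QED", "SAScore")) {
  properties <- intersect(properties,
                          intersect(names(generated), names(reference)))
  if (length(properties) == 0L) stop("no shared property columns")
  one <- function(df, label) {
    do.call(rbind, lapply(properties, function(p) {
      v <- df[[p]][!is.na(df[[p]])]
      data.frame(set = label, property = p, mean = mean(v), sd = stats::sd(v),
                 q25 = unname(stats::quantile(v, 0.25)),
                 median = stats::median(v),
                 q75 = unname(stats::quantile(v, 0.75)), n = length(v),
                 stringsAsFactors = FALSE)
    }))
  }
  summ <- rbind(one(generated, "generated"), one(reference, "reference"))
  gm <- summ$mean[summ$set == "generated"]
  rm_ <- summ$mean[summ$set == "reference"]
  list(summary = summ, mean_diff = stats::setNames(gm - rm_, properties))
}

#' Evaluate a generated library
#'
#' Computes the three generative metrics (validity over all attempts,
#' uniqueness and novelty over the valid molecules) plus the property
#' report against a reference set.
#'
#' @param library Library data frame from [generate_library()].
#' @param training Character vector of canonical training SMILES.
#' @param reference Optional reference property data frame for the property
#'   report (defaults to none).
#' @param novelty_variant Passed to [novelty()].
#' @return An `eval_report` list: `n_generated`, `n_valid`, `validity`,
#'   `uniqueness`, `novelty`, and `properties` (or `NULL`).
#' @export
eval_library <- function(library, training, reference = NULL,
                         novelty_variant = "fraction_new") {
  stopifnot(is.data.frame(library))
  if (nrow(library) == 0L) stop("empty generated set")
  val <- validity(library)
  uni <- if (any(library$valid)) uniqueness(library) else NA_real_
  nov <- if (any(library$valid)) {
    novelty(library, training, variant = novelty_variant)
  } else NA_real_
  props <- NULL
  if (!is.null(reference) && any(library$valid)) {
    props <- property_report(library[library$valid, , drop = FALSE], reference)
  }
  structure(list(n_generated = nrow(library), n_valid = sum(library$valid),
                 validity = val, uniqueness = uni, novelty = nov,
                 properties = props),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("n = %d attempts, %d valid\n", x$n_generated, x$n_valid))
  cat(sprintf("Val.\tUni.\tNov.\n%.3f\t%.3f\t%.3f\n",
              x$validity, x$uniqueness, x$novelty))
  if (!is.null(x$properties)) {
    cat("\nproperty means (generated - reference):\n")
    print(round(x$properties$mean_diff, 3))
  }
  invisible(x)
}

#' Most similar library molecules to a reference
#'
#' Ranks the valid molecules of a library by ECFP4 Tanimoto similarity to a
#' reference molecule, descending, with ties broken by canonical-SMILES
#' lexicographic order. Duplicated canonical forms are ranked once.
#'
#' @param library Library data frame or character vector of valid SMILES.
#' @param reference Reference SMILES (must be valid).
#' @param k Number of hits to return; if larger than the library, all are
#'   returned and the result carries `attr(, "truncated") == TRUE`.
#' @return Data frame with columns `smiles` and `similarity`, `k` rows.
#' @export
nearest_to_reference <- function(library, reference, k = 10L) {
  smiles <- unique(valid_canonical(library))
  stopifnot(k >= 0)
  if (k == 0L) {
    return(data.frame(smiles = character(0), similarity = numeric(0)))
  }
  if (length(smiles) == 0L) stop("no valid molecules in library")
  sims <- ecfp4_tanimoto(smiles, reference)
  ord <- order(-sims, smiles, method = "radix")
  truncated <- k > length(smiles)
  take <- ord[seq_len(min(k, length(smiles)))]
  out <- data.frame(smiles = smiles[take], similarity = sims[take],
                    stringsAsFactors = FALSE)
  if (truncated) attr(out, "truncated") <- TRUE
  out
}
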