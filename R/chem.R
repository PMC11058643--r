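# Chemistry layer: every descriptor, canonical form and fingerprint is
# computed by RDKit through the bundled batch helper, so R-side results are
# exactly the toolkit's. Calls are vectorized; one subprocess per batch.

chemtools_path <- function() {
  p <- system.file("python", "chemtools.py", package = "molcvae")
  if (!nzchar(p)) stop("chemtools.py not found; is molcvae installed?")
  p
}

python_bin <- function() {
  p <- Sys.which("python")
  if (!nzchar(p)) p <- Sys.which("python3")
  if (!nzchar(p)) stop("no 'python' interpreter with RDKit found on PATH")
  p
}

run_chemtools <- function(cmd, smiles, extra_file = NULL) {
  infile <- tempfile("chem_in_"); outfile <- tempfile("chem_out_")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  writeLines(smiles, infile)
  args <- c(chemtools_path(), cmd, infile, outfile, extra_file)
  status <- system2(python_bin(), shQuote(args), stdout = FALSE, stderr = "")
  if (!identical(status, 0L)) {
    stop(sprintf("chemistry helper failed (subcommand '%s', exit %d)", cmd, status))
  }
  jsonlite::fromJSON(outfile, simplifyVector = TRUE)
}

#' Canonicalize SMILES strings
#'
#' Maps each string to the RDKit canonical SMILES of the molecule it
#' denotes. Syntactically or chemically invalid input yields `NA` (the
#' invalid marker), never an error, so the function doubles as a validity
#' test. Canonicalization is idempotent and stereochemistry-preserving.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES, `NA` where invalid.
#' @examples \dontrun{canonicalize(c("OCC", "CCO", "C("))}
#' @export
canonicalize <- function(smiles) {
  if (length(smiles) == 0L) return(character(0))
  stopifnot(is.character(smiles))
  out <- rep(NA_character_, length(smiles))
  ok <- !is.na(smiles) & nzchar(smiles)
  if (any(ok)) {
    res <- run_chemtools("canonicalize", smiles[ok])
    out[ok] <- unlist_null(res$canonical)
  }
  out
}

#' Test SMILES validity
#'
#' A SMILES is valid when RDKit can parse and sanitize it.
#'
#' @inheritParams canonicalize
#' @return Logical vector.
#' @export
is_valid_smiles <- function(smiles) !is.na(canonicalize(smiles))

#' Compute molecular properties
#'
#' Computes the four descriptors used throughout the package with RDKit:
#' `logP` (Crippen octanol-water partition estimate, unitless), `MolWt`
#' (molecular weight, g/mol), `QED` (quantitative estimate of
#' drug-likeness, in \[0, 1\]) and `SAScore` (fragment-contribution
#' synthetic-accessibility score, in \[1, 10\]; low is easy to make).
#'
#' @param smiles Character vector of valid SMILES.
#' @return Data frame with columns `smiles`, `canonical`, `logP`, `MolWt`,
#'   `QED`, `SAScore`, one row per input.
#' @export
compute_properties <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) > 0L)
  res <- run_chemtools("properties", smiles)
  canon <- unlist_null(res$canonical)
  if (anyNA(canon)) {
    stop(sprintf("invalid SMILES: %s",
                 paste(smiles[is.na(canon)], collapse = ", ")))
  }
  data.frame(
    smiles = smiles, canonical = canon,
    logP = as.numeric(unlist_null(res$logP)),
    MolWt = as.numeric(unlist_null(res$MolWt)),
    QED = as.numeric(unlist_null(res$QED)),
    SAScore = as.numeric(unlist_null(res$SAScore)),
    stringsAsFactors = FALSE
  )
}

#' ECFP4 Tanimoto similarity to a reference molecule
#'
#' Radius-2 Morgan circular fingerprints (2048 bits) compared by the
#' Tanimoto coefficient (bit-set intersection over union).
#'
#' @param smiles Character vector of SMILES to score.
#' @param reference A single valid reference SMILES.
#' @return Numeric vector of similarities in \[0, 1\].
#' @export
ecfp4_tanimoto <- function(smiles, reference) {
  stopifnot(is.character(smiles), length(smiles) > 0L,
            is.character(reference), length(reference) == 1L)
  reffile <- tempfile("chem_ref_")
  on.exit(unlink(reffile), add = TRUE)
  writeLines(reference, reffile)
  res <- tryCatch(
    run_chemtools("tanimoto", smiles, extra_file = reffile),
    error = function(e) stop("invalid reference SMILES: ", reference)
  )
  sims <- as.numeric(unlist_null(res$similarity))
  if (anyNA(sims)) {
    stop(sprintf("invalid SMILES: %s",
                 paste(smiles[is.na(sims)], collapse = ", ")))
  }
  sims
}

# jsonlite returns a list with NULLs when any entry is null; flatten to NA.
unlist_null <- function(x) {
  if (is.list(x)) {
    vapply(x, function(e) if (is.null(e)) NA else e,
           if (all(vapply(x, function(e) is.null(e) || is.character(e), TRUE)))
             NA_character_ else NA_real_)
  } else x
}
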