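#' Read and write SMILES flat files
#'
#' One SMILES per line, UTF-8, no header. Blank lines are dropped on read.
#'
#' @param path File path.
#' @return `read_smiles_file()` returns a character vector (possibly empty).
#' @export
read_smiles_file <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines[nzchar(trimws(lines))]
}

#' @rdname read_smiles_file
#' @param corpus Character vector of SMILES.
#' @export
write_smiles_file <- function(corpus, path) {
  stopifnot(is.character(corpus))
  writeLines(corpus, path, useBytes = TRUE)
  invisible(path)
}

#' Read a SMILES-plus-properties CSV
#'
#' Expects a header row with a `smiles` column; any subset of the property
#' columns `logP`, `MolWt`, `QED`, `SAScore` (and, for activity tables,
#' `pIC50`/`pEC50`) may follow. Non-numeric entries in a numeric column are
#' reported with their line number.
#'
#' @param path CSV path.
#' @param require Character vector of column names that must be present.
#' @return Data frame with a `smiles` character column and numeric property
#'   columns.
#' @export
read_property_csv <- function(path, require = character(0)) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"smiles" %in% names(df)) stop("missing required column: smiles")
  missing <- setdiff(require, names(df))
  if (length(missing)) {
    stop("missing property column(s): ", paste(missing, collapse = ", "))
  }
  for (col in setdiff(names(df), "smiles")) {
    if (is.character(df[[col]])) {
      conv <- suppressWarnings(as.numeric(df[[col]]))
      bad <- which(is.na(conv) & nzchar(trimws(df[[col]])))
      if (length(bad)) {
        stop(sprintf("malformed value in column '%s' at line %d of %s",
                     col, bad[1] + 1L, path))  # +1 for the header row
      }
      df[[col]] <- conv
    }
  }
  df
}

#' @rdname read_property_csv
#' @param df Data frame with a `smiles` column.
#' @export
write_property_csv <- function(df, path) {
  stopifnot(is.data.frame(df), "smiles" %in% names(df))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
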