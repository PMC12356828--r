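#' Read a typed table with dialect normalization
#'
#' Canonical table reader for the pipeline. Tables are tab-separated with a
#' header row (CSV accepted on read); the Unicode minus sign (U+2212), as
#' printed in typeset tables, is normalized to ASCII hyphen-minus before
#' parsing, and numeric parsing is locale-independent.
#'
#' @param path path to a TSV or CSV file.
#' @param required_cols character vector of column names that must be
#'   present; a missing column is an error naming both column and file.
#' @param numeric_cols character vector of columns coerced to numeric after
#'   minus-sign normalization. Values that fail to parse are an error.
#' @param sep field separator; `NULL` (default) auto-detects tab vs comma
#'   from the header line.
#' @return a `data.frame`, row order preserved, strings not factored.
#' @export
load_table <- function(path, required_cols = character(), numeric_cols = character(),
                       sep = NULL) {
  if (!file.exists(path))
    abort(sprintf("file not found: %s", path), "cnstriage_io_error")
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- gsub("−", "-", lines)
  if (!length(lines)) abort(sprintf("empty file: %s", path), "cnstriage_io_error")
  if (is.null(sep))
    sep <- if (grepl("\t", lines[[1L]])) "\t" else ","
  nfield <- lengths(strsplit(lines, sep, fixed = TRUE))
  bad <- which(nfield != nfield[[1L]])
  if (length(bad))
    abort(sprintf("malformed row in %s at line %d: expected %d fields, got %d",
                  path, bad[[1L]], nfield[[1L]], nfield[[bad[[1L]]]]),
          "cnstriage_io_error")
  df <- utils::read.table(text = lines, sep = sep, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "")
  missing <- setdiff(required_cols, names(df))
  if (length(missing))
    abort(sprintf("missing column '%s' in %s", missing[[1L]], path),
          "cnstriage_io_error")
  for (cn in intersect(numeric_cols, names(df))) {
    v <- suppressWarnings(as.numeric(df[[cn]]))
    newly_na <- is.na(v) & !is.na(df[[cn]]) & !(df[[cn]] %in% c("NA", "", "NaN"))
    if (any(newly_na))
      abort(sprintf("column '%s' in %s has non-numeric value '%s'",
                    cn, path, df[[cn]][which(newly_na)[1L]]),
            "cnstriage_io_error")
    df[[cn]] <- v
  }
  # remaining all-numeric-looking columns stay character unless requested
  df
}

#' Write a table in the canonical TSV dialect
#'
#' @param df data.frame to write.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}
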