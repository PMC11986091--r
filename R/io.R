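# Tabular IO helpers shared by the loaders and the CLI. All files are UTF-8;
# a leading byte-order mark is tolerated on input and never written.

read_tsv_checked <- function(path, required_cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          comment.char = "#", quote = "",
                          colClasses = "character",
                          fileEncoding = "UTF-8-BOM",
                          check.names = FALSE,
                          stringsAsFactors = FALSE)
  missing <- setdiff(required_cols, names(df))
  if (length(missing) > 0L) {
    stop("file ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "),
         " (found: ", paste(names(df), collapse = ", "), ")")
  }
  df
}

# temp-file-then-rename so a failed run leaves no partial output
write_atomic <- function(writer, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir)
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

write_tsv_atomic <- function(df, path) {
  write_atomic(function(tmp) {
    utils::write.table(df, tmp, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }, path)
}

write_delim_atomic <- function(df, path, delimiter = ",") {
  write_atomic(function(tmp) {
    utils::write.table(df, tmp, sep = delimiter, quote = TRUE,
                       row.names = FALSE, qmethod = "double",
                       fileEncoding = "UTF-8")
  }, path)
}

write_lines_atomic <- function(lines, path) {
  write_atomic(function(tmp) {
    con <- file(tmp, open = "wb")
    on.exit(close(con), add = TRUE)
    writeLines(lines, con, useBytes = TRUE)
  }, path)
}

#' Read a table of free-text medication entries
#'
#' Reads a delimited UTF-8 file (byte-order marks and CRLF line endings are
#' tolerated) holding one medication administration event per row. Only the
#' entry column is standardized downstream; other columns are ignored.
#'
#' @param path Path to a CSV/TSV file.
#' @param delimiter Field delimiter, a single character (default `","`).
#' @param column Name of the column holding the free text; `NULL` (default)
#'   takes the first column.
#' @return A data.frame with the original columns; the attribute
#'   `"entry_column"` names the selected column.
#' @export
read_entries <- function(path, delimiter = ",", column = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          quote = "\"", colClasses = "character",
                          fileEncoding = "UTF-8-BOM", check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  if (ncol(df) == 0L) stop("input file has no columns: ", path)
  if (is.null(column)) {
    column <- names(df)[1L]
  } else if (!column %in% names(df)) {
    stop("input column '", column, "' not found; available columns: ",
         paste(names(df), collapse = ", "))
  }
  attr(df, "entry_column") <- column
  df
}
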