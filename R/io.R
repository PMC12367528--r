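#' Read a delimited subject-level table
#'
#' Reads a tab- or comma-separated table with a header row. The delimiter is
#' auto-detected by default and can be forced. Subject-level tables must carry
#' a `subject_id` key column; duplicated ids are an error.
#'
#' @param path Path to a delimited text file with a header row.
#' @param required_cols Character vector of columns that must be present.
#' @param sep `"auto"` (default), `"\t"` or `","`.
#' @param id_col Name of the key column checked for duplicates; set to `NULL`
#'   for tables that are not subject-level.
#' @return A `data.frame`.
#' @export
read_table <- function(path, required_cols = NULL, sep = "auto",
                       id_col = "subject_id") {
  if (!file.exists(path)) stop_data("file not found: ", path)
  dt <- data.table::fread(path, sep = sep, header = TRUE, data.table = FALSE)
  missing <- setdiff(required_cols, names(dt))
  if (length(missing))
    stop_data("missing required columns in ", basename(path), ": ",
              paste(missing, collapse = ", "))
  if (!is.null(id_col) && id_col %in% names(dt)) {
    dup <- dt[[id_col]][duplicated(dt[[id_col]])]
    if (length(dup))
      stop_data("duplicated ", id_col, " in ", basename(path), ": ",
                paste(unique(head(dup, 5)), collapse = ", "))
  }
  dt
}

#' Write a delimited table
#'
#' Values are written with full double precision so that a write/read
#' round-trip is stable to at least 12 significant digits.
#'
#' @param x A data frame or matrix.
#' @param path Output path.
#' @param sep Field delimiter, tab by default.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, sep = "\t") {
  x <- as.data.frame(x)
  data.table::fwrite(x, path, sep = sep, quote = FALSE)
  invisible(path)
}
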