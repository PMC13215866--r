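# Survey table I/O. CSV dialect is pinned: UTF-8, comma separator, "."
# decimal, one header row, one row per household.

#' Read a household survey table
#'
#' @param path CSV file path.
#' @param schema optional named character vector mapping column names to one
#'   of `"binary"` (0/1), `"count"` (non-negative integer), `"positive"`
#'   (strictly positive numeric) or `"numeric"`. Schema columns must exist;
#'   values are type-checked with the offending row and column named. Rows
#'   with missing values in schema columns (all columns when no schema) are
#'   dropped with a message.
#' @return data.frame.
#' @export
read_survey <- function(path, schema = NULL) {
  if (!file.exists(path)) abort("file not found: %s", path)
  table <- read.csv(path, check.names = FALSE, fileEncoding = "UTF-8")
  check_cols <- if (is.null(schema)) names(table) else names(schema)
  unknown <- setdiff(check_cols, names(table))
  if (length(unknown) > 0) {
    abort("unknown column(s) in schema: %s", paste(unknown, collapse = ", "))
  }
  complete <- stats::complete.cases(table[check_cols])
  dropped <- sum(!complete)
  if (dropped > 0) {
    message(dropped, " incomplete row(s) excluded (missing values in ",
            "schema columns)")
    table <- table[complete, , drop = FALSE]
    rownames(table) <- NULL
  }
  if (!is.null(schema)) {
    for (col in names(schema)) {
      x <- table[[col]]
      if (!is.numeric(x)) {
        abort("column '%s' must be numeric (type %s)", col, schema[[col]])
      }
      bad <- switch(schema[[col]],
                    binary = which(!x %in% c(0, 1)),
                    count = which(x < 0 | x != floor(x)),
                    positive = which(x <= 0),
                    numeric = integer(0),
                    abort("unknown schema type '%s'", schema[[col]]))
      if (length(bad) > 0) {
        abort("column '%s' violates type '%s' at row %d (value %s)",
              col, schema[[col]], bad[1], format(x[bad[1]]))
      }
    }
  }
  table
}

#' Write a household survey table
#'
#' @param table data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_survey <- function(table, path) {
  write.csv(table, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
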