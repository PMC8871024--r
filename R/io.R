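# Cohort CSV round-trip. Numeric columns are serialized at full double
# precision (%.17g) so write-then-read is an exact identity.

#' Write a cohort table to CSV
#'
#' One header row, columns in schema order, categorical values as labels,
#' UTF-8, "." decimal separator. Continuous values are written at full
#' precision so that [read_cohort()] reproduces them exactly.
#'
#' @param cohort a cohort data frame.
#' @param path output file path.
#' @param schema a [cohort_schema()].
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path, schema = cohort_schema()) {
  validate_cohort(cohort, schema)
  cols <- c(schema$features$name, schema$outcome)
  out <- cohort[, cols, drop = FALSE]
  for (cn in cols) {
    if (is.numeric(out[[cn]])) out[[cn]] <- sprintf("%.17g", out[[cn]])
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a cohort table from CSV
#'
#' Parses and validates a cohort CSV written by [write_cohort()] (or prepared
#' externally with the same layout). Errors name the offending row and column:
#' unknown columns, unparseable numbers, out-of-schema category labels, and
#' outcome values outside the admissible range are all rejected.
#'
#' @param path CSV file path.
#' @param schema a [cohort_schema()].
#' @return A validated cohort data frame of class `ovr_cohort`.
#' @export
read_cohort <- function(path, schema = cohort_schema()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8", check.names = FALSE)
  cols <- c(schema$features$name, schema$outcome)
  missing_cols <- setdiff(cols, names(df))
  if (length(missing_cols))
    stop("cohort CSV is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  num_cols <- c(schema$features$name[schema$features$kind == "continuous"],
                schema$outcome)
  for (cn in num_cols) {
    if (!is.numeric(df[[cn]])) {
      v <- suppressWarnings(as.numeric(df[[cn]]))
      if (anyNA(v))
        stop(sprintf("unparseable value '%s' in column '%s' (row %d)",
                     df[[cn]][which(is.na(v))[1]], cn, which(is.na(v))[1]))
      df[[cn]] <- v
    }
  }
  df <- df[, cols, drop = FALSE]
  validate_cohort(df, schema)
  class(df) <- c("ovr_cohort", "data.frame")
  df
}
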