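#' Read and write SBR record tables
#'
#' CSV serialisation of the SBR record layout (one row per
#' subject-side-structure measurement) with column and type validation;
#' malformed files raise an error naming the offending column or row.
#'
#' @param records SBR record data.frame (see [small_voi_sbr()]).
#' @param path CSV file path.
#' @return `path` (write) or the validated data.frame (read).
#' @export
write_sbr_table <- function(records, path) {
  need <- sbr_table_columns()
  missing <- setdiff(need, names(records))
  if (length(missing))
    stop("records are missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  utils::write.csv(records[, need], path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_sbr_table
#' @export
read_sbr_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  header <- utils::read.csv(path, nrows = 1, stringsAsFactors = FALSE)
  classes <- c(subject_id = "character", scanner_id = "character")
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = classes[names(classes) %in% names(header)])
  need <- sbr_table_columns()
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("SBR table ", path, " is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(suppressWarnings(as.numeric(df$measured_sbr))))
  if (length(bad))
    stop("SBR table ", path, ": non-numeric measured_sbr at data row ",
         bad[1], call. = FALSE)
  df$measured_sbr <- as.numeric(df$measured_sbr)
  df$calibrated_sbr <- suppressWarnings(as.numeric(df$calibrated_sbr))
  df
}

sbr_table_columns <- function() {
  c("subject_id", "age", "scanner_id", "mode", "quantifier", "side",
    "structure", "measured_sbr", "calibrated_sbr")
}
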