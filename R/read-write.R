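#' Read a paired-measurement dataset
#'
#' Reads the package's CSV dialect: one row per (subject, time point, method,
#' replicate), columns `subject_id, timepoint, method, replicate_index, ci,
#' svi, svri, svv, hr, sbp, dpdt`. Empty cells are absent values. Every row
#' is validated against the record invariants; malformed rows are reported
#' with their line numbers.
#'
#' @param path Path to a CSV file.
#' @return A tibble of validated measurement records. `timepoint` is an
#'   ordered factor over baseline, rosc15, rosc30, rosc60.
#' @seealso [write_measurements()], [validate_measurements()]
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  header <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                                  show_col_types = FALSE))
  missing <- setdiff(MEASUREMENT_COLS, header)
  if (length(missing)) {
    abort(paste0("schema error: missing mandatory column(s): ",
                 paste(missing, collapse = ", ")))
  }
  df <- readr::read_csv(
    path,
    col_types = readr::cols(
      subject_id = readr::col_character(),
      timepoint = readr::col_character(),
      method = readr::col_character(),
      replicate_index = readr::col_integer(),
      .default = readr::col_double()
    ),
    show_col_types = FALSE
  )
  validate_measurements(df)
}

#' Validate measurement records
#'
#' Checks the record invariants: recognised time point and method labels,
#' positive replicate indices, strictly positive `ci`, `svi`, `svri`, `hr`,
#' `sbp` where present, `svv` within \[0, 100\], and uniqueness of the
#' (subject, timepoint, method, replicate) key. All violations are collected
#' and reported together with row numbers.
#'
#' @param df A data frame with the measurement column schema.
#' @return The validated tibble (invisibly identical data, `timepoint` as a
#'   factor), or an error listing every offending row and field.
#' @export
validate_measurements <- function(df) {
  df <- tibble::as_tibble(df)
  missing <- setdiff(MEASUREMENT_COLS, names(df))
  if (length(missing)) {
    abort(paste0("schema error: missing mandatory column(s): ",
                 paste(missing, collapse = ", ")))
  }
  problems <- character()
  note <- function(rows, msg) {
    if (any(rows)) {
      problems <<- c(problems, paste0(
        "row ", paste(which(rows), collapse = ", "), ": ", msg))
    }
  }
  note(is.na(df$subject_id) | df$subject_id == "", "empty subject_id")
  note(!is.na(df$timepoint) & !df$timepoint %in% TIMEPOINTS,
       paste0("timepoint must be one of ", paste(TIMEPOINTS, collapse = "|")))
  note(is.na(df$timepoint), "missing timepoint")
  note(!is.na(df$method) & !df$method %in% c("reference", "test"),
       "method must be reference|test")
  note(is.na(df$method), "missing method")
  note(is.na(df$replicate_index) | df$replicate_index < 1,
       "replicate_index must be a positive integer")
  for (v in POSITIVE_VARS) {
    note(!is.na(df[[v]]) & df[[v]] <= 0,
         paste0(v, " must be strictly positive"))
  }
  note(!is.na(df$svv) & (df$svv < 0 | df$svv > 100),
       "svv must lie in [0, 100]")
  key <- paste(df$subject_id, df$timepoint, df$method, df$replicate_index)
  note(duplicated(key) | duplicated(key, fromLast = TRUE),
       "duplicate (subject, timepoint, method, replicate) key")
  if (length(problems)) {
    abort(paste0("validation error:\n  ",
                 paste(problems, collapse = "\n  ")))
  }
  df$timepoint <- timepoint_factor(df$timepoint)
  df
}

#' Write a measurement dataset
#'
#' Writes records in the same CSV dialect that [read_measurements()] reads,
#' so a write-then-read round trip reproduces the dataset exactly. Absent
#' values become empty cells.
#'
#' @param df A tibble of measurement records.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(df, path) {
  out <- dplyr::mutate(
    tibble::as_tibble(df)[, MEASUREMENT_COLS],
    timepoint = as.character(.data$timepoint)
  )
  readr::write_csv(out, path, na = "")
  invisible(path)
}
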