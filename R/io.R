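athlete_cols <- function() {
  single <- setdiff(cca_task_ids(), "long_jump")
  c(
    "participant_id", "age", "sex", "session",
    paste0(rep(single, each = 2), c("_raw", "_errors")),
    paste0("long_jump_d", 1:3), paste0("long_jump_v", 1:3),
    "long_jump_errors"
  )
}

retest_cols <- function() {
  c(
    "participant_id", "age", "sex", "session", "interval_months",
    paste0(rep(cca_task_ids(), each = 2), c("_raw", "_errors"))
  )
}

validate_records <- function(records, required, path) {
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    rlang::abort(
      paste0(
        path, ": missing column(s): ", paste(missing_cols, collapse = ", ")
      ),
      class = "ccakit_schema_error"
    )
  }
  problems <- character(0)
  row_issue <- function(bad, what) {
    if (any(bad, na.rm = TRUE)) {
      rows <- which(bad)
      problems <<- c(problems, paste0(
        what, " (row", if (length(rows) > 1) "s" else "", " ",
        paste(utils::head(rows, 5), collapse = ", "),
        if (length(rows) > 5) ", ..." else "", ")"
      ))
    }
  }
  row_issue(
    is.na(records$participant_id) | records$participant_id == "",
    "missing participant_id"
  )
  row_issue(is.na(records$age) | records$age < 0, "missing or negative age")
  row_issue(
    !records$sex %in% c("male", "female"),
    "sex must be 'male' or 'female'"
  )
  for (col in grep("_raw$|_d[123]$", required, value = TRUE)) {
    row_issue(records[[col]] < 0, paste0("negative ", col))
  }
  for (col in grep("_errors$", required, value = TRUE)) {
    row_issue(
      is.na(records[[col]]) | records[[col]] < 0,
      paste0("missing or negative ", col)
    )
  }
  if (length(problems) > 0) {
    rlang::abort(
      paste0(path, ": invalid records: ", paste(problems, collapse = "; ")),
      class = "ccakit_schema_error"
    )
  }
  records
}

#' Read and write athlete-record CSV files
#'
#' The normative (cross-sectional) layout has one row per
#' participant-session with a mandatory header: `participant_id`, `age`,
#' `sex`, `session`, `<task>_raw` and `<task>_errors` for the five
#' single-trial tasks, and the standing long jump as three distance columns
#' (`long_jump_d1..d3`), three landing-validity flags (`long_jump_v1..v3`)
#' and `long_jump_errors`. The paired (test-retest) layout adds
#' `interval_months` and carries one `<task>_raw` value per task and
#' session (best distance for the long jump). Files are comma-separated,
#' UTF-8, dot-decimal. Reading validates the schema and rejects negative
#' measurements or error counts and missing demographics with row-addressed
#' messages.
#'
#' @param sample,pairs Tibble in the corresponding layout.
#' @param path CSV file path.
#' @return The tibble (readers) or `path`, invisibly (writers).
#' @export
read_athlete_csv <- function(path) {
  records <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_records(records, athlete_cols(), path)
}

#' @rdname read_athlete_csv
#' @export
write_athlete_csv <- function(sample, path) {
  readr::write_csv(sample, path)
  invisible(path)
}

#' @rdname read_athlete_csv
#' @export
read_retest_csv <- function(path) {
  records <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_records(records, retest_cols(), path)
}

#' @rdname read_athlete_csv
#' @export
write_retest_csv <- function(pairs, path) {
  readr::write_csv(pairs, path)
  invisible(path)
}
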