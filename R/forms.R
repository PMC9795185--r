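#' Construct a scoring form
#'
#' A scoring form holds the raw-measure cut points that turn performances
#' into score bins, for one stratum (age band x sex) or pooled across the
#' whole normative sample, together with provenance describing how the cut
#' points were derived.
#'
#' @param thresholds Named list, one ascending numeric vector of cut points
#'   per task: 3 cut points for `quartile_5pt` forms, 1 or 2 for
#'   `mean_sd_4pt` forms.
#' @param method `"quartile_5pt"` (the final 0-4 response scale) or
#'   `"mean_sd_4pt"` (the legacy 4-point scale).
#' @param stratum Either the string `"pooled"` or a list with `age_band`
#'   (`"9-12"` or `"13-18"`) and `sex` (`"male"`/`"female"`).
#' @param provenance Optional list recording `sample_id`, per-task `n_used`
#'   and the derivation `seed`.
#' @param degenerate Named logical vector flagging tasks whose derivation
#'   sample had zero spread (tied cut points).
#' @return A `cca_scoring_form`.
#' @export
scoring_form <- function(thresholds,
                         method = c("quartile_5pt", "mean_sd_4pt"),
                         stratum = "pooled",
                         provenance = list(),
                         degenerate = NULL) {
  method <- match.arg(method)
  if (!is.list(thresholds) || is.null(names(thresholds))) {
    rlang::abort("`thresholds` must be a named list of numeric vectors.",
      class = "ccakit_form_error"
    )
  }
  bad <- setdiff(names(thresholds), cca_task_ids())
  if (length(bad) > 0) {
    rlang::abort(paste0("Unknown task id(s): ", paste(bad, collapse = ", ")),
      class = "ccakit_form_error"
    )
  }
  expected_len <- if (method == "quartile_5pt") 3L else c(1L, 2L)
  for (task in names(thresholds)) {
    th <- thresholds[[task]]
    if (!length(th) %in% expected_len) {
      rlang::abort(
        paste0(
          "Task '", task, "': ", length(th), " cut point(s) supplied; ",
          "method '", method, "' expects ",
          paste(expected_len, collapse = " or "), "."
        ),
        class = "ccakit_form_error"
      )
    }
    if (is.unsorted(th)) {
      rlang::abort(
        paste0("Task '", task, "': cut points must be ascending."),
        class = "ccakit_form_error"
      )
    }
  }
  if (is.null(degenerate)) {
    degenerate <- stats::setNames(
      vapply(thresholds, function(th) any(duplicated(th)), logical(1)),
      names(thresholds)
    )
  }
  structure(
    list(
      method = method,
      stratum = stratum,
      thresholds = thresholds,
      provenance = provenance,
      degenerate = degenerate
    ),
    class = "cca_scoring_form"
  )
}

form_thresholds <- function(form, task) {
  stopifnot(inherits(form, "cca_scoring_form"))
  th <- form$thresholds[[task]]
  if (is.null(th)) {
    rlang::abort(
      paste0("Scoring form has no cut points for task '", task, "'."),
      class = "ccakit_form_error"
    )
  }
  th
}

#' @export
print.cca_scoring_form <- function(x, ...) {
  cat("<cca_scoring_form>", x$method, "\n")
  if (identical(x$stratum, "pooled")) {
    cat("  stratum: pooled\n")
  } else {
    cat("  stratum:", x$stratum$sex, x$stratum$age_band, "\n")
  }
  for (task in names(x$thresholds)) {
    cat(
      sprintf(
        "  %-18s %s%s\n", task,
        paste(signif(x$thresholds[[task]], 5), collapse = ", "),
        if (isTRUE(x$degenerate[[task]])) " [degenerate]" else ""
      )
    )
  }
  invisible(x)
}

#' Write and read scoring forms as JSON
#'
#' Forms are serialised as a versioned JSON document with full double
#' precision so that a write/read round trip reproduces cut points
#' bit-exactly.
#'
#' @param forms A `cca_scoring_form` or a named list of them.
#' @param path File path for the JSON document.
#' @return `write_scoring_forms()` returns `path` invisibly;
#'   `read_scoring_forms()` returns a `cca_scoring_form` or a named list of
#'   forms, mirroring what was written.
#' @export
write_scoring_forms <- function(forms, path) {
  single <- inherits(forms, "cca_scoring_form")
  form_list <- if (single) list(pooled = forms) else forms
  doc <- list(
    schema = "ccakit/scoring-forms",
    schema_version = 1L,
    single = single,
    forms = lapply(form_list, unclass)
  )
  # 17 significant digits round-trips IEEE doubles exactly
  jsonlite::write_json(doc, path,
    auto_unbox = TRUE, digits = I(17), pretty = TRUE
  )
  invisible(path)
}

#' @rdname write_scoring_forms
#' @export
read_scoring_forms <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!identical(doc$schema, "ccakit/scoring-forms")) {
    rlang::abort("Not a ccakit scoring-form document.",
      class = "ccakit_form_error"
    )
  }
  rebuild <- function(f) {
    stratum <- f$stratum
    if (is.list(stratum) && length(stratum) == 0) stratum <- "pooled"
    scoring_form(
      thresholds = lapply(f$thresholds, as.numeric),
      method = f$method,
      stratum = stratum,
      provenance = f$provenance,
      degenerate = unlist(f$degenerate)
    )
  }
  forms <- lapply(doc$forms, rebuild)
  if (isTRUE(doc$single)) forms[[1]] else forms
}
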