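#' Assign a raw performance to a score bin
#'
#' Partitions the raw measurement axis into four bins using an ordered set of
#' cut points and returns the 1-4 performance bin: 4 for the best bin
#' (fastest times, longest jumps, most repetitions), 1 for the worst. Error
#' modifications are applied separately by [apply_error_rule()].
#'
#' Cut points are always supplied in ascending raw-measure order; `direction`
#' states which end of the axis is better. A value exactly equal to a cut
#' point is assigned the better adjacent bin, so e.g. a standing long jump of
#' exactly 1.5 m under a form whose top cut point is 1.5 m scores 4.
#'
#' @param raw Numeric vector of raw measurements (seconds, repetitions or
#'   metres, matching the form).
#' @param thresholds Ascending numeric cut points; length 3 for the 5-point
#'   (0-4) quartile forms, 1 or 2 for the legacy 4-point mean±SD forms.
#' @param direction `"lower_better"` (timed tasks) or `"higher_better"`
#'   (repetitions, distance).
#' @return Integer vector of bin scores in `1:(length(thresholds) + 1)`.
#' @examples
#' bin_score(1.5, c(1.0, 1.25, 1.5), "higher_better") # top bin
#' bin_score(14.2, c(8, 10, 12), "lower_better") # slowest bin
#' @export
bin_score <- function(raw, thresholds,
                      direction = c("lower_better", "higher_better")) {
  direction <- match.arg(direction)
  if (length(thresholds) < 1 || anyNA(thresholds)) {
    rlang::abort("`thresholds` must be a non-empty numeric vector.",
      class = "ccakit_form_error"
    )
  }
  if (is.unsorted(thresholds)) {
    rlang::abort(
      "`thresholds` must be ordered ascending in raw-measure units.",
      class = "ccakit_form_error"
    )
  }
  if (anyNA(raw)) {
    rlang::abort("`raw` contains missing values.",
      class = "ccakit_missing_data_error"
    )
  }
  cmp <- if (direction == "lower_better") {
    outer(raw, thresholds, `<=`)
  } else {
    outer(raw, thresholds, `>=`)
  }
  as.integer(1L + rowSums(cmp))
}

#' Apply a task's error rule to a performance bin score
#'
#' Returns 0 when the error count reaches the task's auto-zero threshold;
#' otherwise the bin score capped at the maximum attainable score for that
#' error count. With zero errors the bin score passes through unchanged.
#'
#' @param bin_score Integer vector of performance bins (1-4).
#' @param error_count Non-negative integer vector of recorded errors.
#' @param rule A `cca_error_rule`, see [cca_error_rules()].
#' @return Integer item scores in 0-4.
#' @examples
#' rule <- cca_error_rules()$backwards_tandem
#' apply_error_rule(4, 5, rule) # five errors: automatic 0
#' apply_error_rule(4, 1, rule) # one error caps the score at 3
#' @export
apply_error_rule <- function(bin_score, error_count, rule) {
  stopifnot(inherits(rule, "cca_error_rule"))
  if (any(error_count < 0) || any(error_count != floor(error_count))) {
    rlang::abort("`error_count` must be non-negative integers.",
      class = "ccakit_input_error"
    )
  }
  n <- max(length(bin_score), length(error_count))
  bin_score <- rep_len(as.integer(bin_score), n)
  error_count <- rep_len(error_count, n)
  idx <- pmin(error_count, length(rule$caps) - 1L) + 1L
  capped <- pmin(bin_score, rule$caps[idx])
  as.integer(ifelse(error_count >= rule$zero_score_at, 0L, capped))
}

#' Score the Standing Long Jump from its three trials
#'
#' The best distance among trials with a valid two-foot take-off and landing
#' is binned against the form's cut points. If no trial has a valid landing
#' the item score is 0.
#'
#' @param distances Numeric vector of exactly 3 jump distances in metres.
#' @param valid Logical vector of exactly 3 landing-validity flags.
#' @param thresholds Ascending cut points in metres.
#' @return Integer item score 0-4.
#' @examples
#' score_long_jump(c(1.2, 1.5, 1.3), c(TRUE, TRUE, TRUE), c(1.0, 1.25, 1.5))
#' score_long_jump(c(1.2, 1.5, 1.3), c(FALSE, FALSE, FALSE), c(1.0, 1.25, 1.5))
#' @export
score_long_jump <- function(distances, valid, thresholds) {
  if (length(distances) != 3L || length(valid) != 3L) {
    rlang::abort(
      "Standing Long Jump requires exactly 3 trial distances and 3 validity flags.",
      class = "ccakit_input_error"
    )
  }
  if (!any(valid, na.rm = TRUE)) {
    return(0L)
  }
  best <- max(distances[which(valid)], na.rm = TRUE)
  bin_score(best, thresholds, "higher_better")
}

#' Score one task for one participant record
#'
#' Composes [bin_score()] and [apply_error_rule()]: the raw performance is
#' binned against the scoring form's cut points for the task, then capped or
#' zeroed according to the recorded error count. For Standing Long Jump the
#' best valid-landing distance of the three trials is used and landing
#' validity (not the error count) drives the score-0 rule.
#'
#' @param record A one-row tibble in the athlete-record layout (see
#'   [simulate_normative_sample()] for the column schema).
#' @param task Task id, one of [cca_task_ids()].
#' @param form A `cca_scoring_form` containing cut points for `task`.
#' @param rule The task's `cca_error_rule`; defaults to the instrument rule.
#' @return Integer item score 0-4.
#' @export
score_task <- function(record, task, form,
                       rule = cca_error_rules()[[task]]) {
  info <- task_info(task)
  thresholds <- form_thresholds(form, task)
  if (task == "long_jump") {
    d <- as.numeric(record[paste0("long_jump_d", 1:3)])
    v <- as.logical(record[paste0("long_jump_v", 1:3)])
    return(score_long_jump(d, v, thresholds))
  }
  raw_col <- paste0(task, "_raw")
  err_col <- paste0(task, "_errors")
  if (!raw_col %in% names(record) || anyNA(record[[raw_col]])) {
    rlang::abort(
      paste0(
        "Missing raw value for task '", task, "' (participant ",
        record$participant_id %||% "?", ")."
      ),
      class = "ccakit_missing_data_error"
    )
  }
  b <- bin_score(record[[raw_col]], thresholds, info$direction)
  apply_error_rule(b, record[[err_col]], rule)
}

#' Bundle the six item scores into a score result
#'
#' The instrument's summary score is the unweighted sum of the three outcome
#' items (Backwards Tandem Walking, Ins and Outs, Standing Long Jump), giving
#' a 0-12 follow-up score; the three exertion items remain standalone.
#'
#' @param scores Named integer vector (or list) of six item scores 0-4, named
#'   by task id.
#' @return A `cca_score_result`: list with `item_scores`, `outcome_summary`
#'   (0-12) and `exertion_scores`.
#' @examples
#' score_result(c(
#'   jumping_jacks = 4, pylon_obstacle = 3, backwards_tandem = 3,
#'   shuttle_run = 2, ins_and_outs = 2, long_jump = 4
#' ))
#' @export
score_result <- function(scores) {
  scores <- unlist(scores)
  ids <- cca_task_ids()
  missing <- setdiff(ids, names(scores))
  if (length(missing) > 0) {
    rlang::abort(
      paste0("Missing item score(s): ", paste(missing, collapse = ", ")),
      class = "ccakit_missing_data_error"
    )
  }
  scores <- as.integer(scores[ids])
  names(scores) <- ids
  if (any(scores < 0 | scores > 4)) {
    rlang::abort("Item scores must lie in 0-4.", class = "ccakit_input_error")
  }
  outcome <- cca_outcome_items()
  structure(
    list(
      item_scores = scores,
      outcome_summary = sum(scores[outcome]),
      exertion_scores = scores[setdiff(ids, outcome)]
    ),
    class = "cca_score_result"
  )
}

#' @export
print.cca_score_result <- function(x, ...) {
  cat("<cca_score_result>\n")
  cat("  items:", paste(names(x$item_scores), x$item_scores,
    sep = "=", collapse = " "
  ), "\n")
  cat("  outcome summary (0-12):", x$outcome_summary, "\n")
  invisible(x)
}

#' Score every participant-session in a sample
#'
#' Applies the full scoring engine to a sample in the athlete-record layout.
#' With a single (pooled) scoring form every record is scored against it;
#' with a stratified form set each record is scored against the form matching
#' its age band and sex.
#'
#' @param sample Tibble of athlete records (see
#'   [simulate_normative_sample()]).
#' @param forms A `cca_scoring_form` or a named list of four stratified forms
#'   from [build_scoring_forms()].
#' @param rules Error rules, defaulting to [cca_error_rules()].
#' @return Tibble with `participant_id`, `session`, `age`, `sex`, one
#'   `score_<task>` column per task, and `outcome_summary`.
#' @export
score_sample <- function(sample, forms, rules = cca_error_rules()) {
  stratified <- !inherits(forms, "cca_scoring_form")
  out <- sample[, intersect(
    c("participant_id", "session", "age", "sex"),
    names(sample)
  )]
  ids <- cca_task_ids()
  score_cols <- matrix(NA_integer_,
    nrow = nrow(sample), ncol = length(ids),
    dimnames = list(NULL, paste0("score_", ids))
  )
  keys <- if (stratified) stratum_key(sample$age, sample$sex) else
    rep("pooled", nrow(sample))
  for (key in unique(keys)) {
    rows <- which(keys == key)
    form <- if (stratified) forms[[key]] else forms
    if (is.null(form)) {
      rlang::abort(paste0("No scoring form for stratum '", key, "'."),
        class = "ccakit_form_error"
      )
    }
    for (task in ids) {
      info <- task_info(task)
      thresholds <- form_thresholds(form, task)
      if (task == "long_jump") {
        d <- as.matrix(sample[rows, paste0("long_jump_d", 1:3)])
        v <- as.matrix(sample[rows, paste0("long_jump_v", 1:3)])
        sc <- vapply(seq_along(rows), function(i) {
          score_long_jump(d[i, ], as.logical(v[i, ]), thresholds)
        }, integer(1))
      } else {
        b <- bin_score(
          sample[[paste0(task, "_raw")]][rows], thresholds, info$direction
        )
        sc <- apply_error_rule(
          b, sample[[paste0(task, "_errors")]][rows], rules[[task]]
        )
      }
      score_cols[rows, paste0("score_", task)] <- sc
    }
  }
  out <- dplyr::bind_cols(out, tibble::as_tibble(score_cols))
  outcome_cols <- paste0("score_", cca_outcome_items())
  out$outcome_summary <- as.integer(rowSums(out[, outcome_cols]))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stratum_key <- function(age, sex) {
  paste(sex, age_band(age), sep = "_")
}
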