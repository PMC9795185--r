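#' The six Concussion Challenge Assessment tasks
#'
#' Returns the task table for the CCA: three coordination tasks (Jumping
#' Jacks, Backwards Tandem Walking, Ins and Outs), two speed-and-agility
#' tasks (Pylon Obstacle Course, Modified Shuttle Run) and one strength task
#' (Standing Long Jump). Each task is measured either as time to complete
#' (seconds, lower is better), repetitions (higher is better) or jump
#' distance (metres, higher is better), alongside a count of performance
#' errors. Standing Long Jump is the only task with three trials; the best
#' valid-landing distance is scored.
#'
#' The `item_class` column records the final partition of the instrument:
#' `outcome` items (Backwards Tandem Walking, Ins and Outs, Standing Long
#' Jump) are summed into the 0-12 follow-up summary score, while `exertion`
#' items (Jumping Jacks, Pylon Obstacle Course, Modified Shuttle Run) are
#' standalone single-time-point aerobic challenge scores.
#'
#' @return A tibble with one row per task: `task_id`, `label`,
#'   `measure_kind`, `direction`, `n_trials`, `domains` (list column),
#'   `item_class`.
#' @examples
#' cca_tasks()
#' @export
cca_tasks <- function() {
  measure_kind <- c(
    "repetitions", "time_seconds", "time_seconds",
    "time_seconds", "time_seconds", "distance_metres"
  )
  tibble::tibble(
    task_id = c(
      "jumping_jacks", "pylon_obstacle", "backwards_tandem",
      "shuttle_run", "ins_and_outs", "long_jump"
    ),
    label = c(
      "Jumping Jacks", "Pylon Obstacle Course", "Backwards Tandem Walking",
      "Modified Shuttle Run", "Ins and Outs", "Standing Long Jump"
    ),
    measure_kind = measure_kind,
    direction = ifelse(measure_kind == "time_seconds",
      "lower_better", "higher_better"
    ),
    n_trials = c(1L, 1L, 1L, 1L, 1L, 3L),
    domains = list(
      "coordination",
      "speed_agility",
      c("coordination", "dynamic_balance"),
      c("speed_agility", "dynamic_balance"),
      "coordination",
      c("strength", "dynamic_balance")
    ),
    item_class = c(
      "exertion", "exertion", "outcome",
      "exertion", "outcome", "outcome"
    )
  )
}

#' @rdname cca_tasks
#' @export
cca_task_ids <- function() cca_tasks()$task_id

#' Outcome and exertion item identifiers
#'
#' @return Character vector of task ids in the requested class.
#' @export
cca_outcome_items <- function() {
  tasks <- cca_tasks()
  tasks$task_id[tasks$item_class == "outcome"]
}

task_info <- function(task) {
  tasks <- cca_tasks()
  if (!task %in% tasks$task_id) {
    rlang::abort(
      paste0(
        "Unknown task id '", task, "'. Valid ids: ",
        paste(tasks$task_id, collapse = ", ")
      ),
      class = "ccakit_config_error"
    )
  }
  tasks[tasks$task_id == task, ]
}

new_error_rule <- function(task_id, zero_score_at, caps) {
  stopifnot(caps[1] == 4L, all(diff(caps) <= 0))
  if (is.finite(zero_score_at)) stopifnot(length(caps) == zero_score_at)
  structure(
    list(task_id = task_id, zero_score_at = zero_score_at, caps = caps),
    class = "cca_error_rule"
  )
}

#' Error-score modification rules for the CCA tasks
#'
#' Performance errors (e.g. touching a pylon, a non-tandem step, missing the
#' start line) modify the raw-performance bin score so that speed or distance
#' is never credited at the expense of accuracy. Each rule has two parts:
#'
#' * `zero_score_at`: the minimum error count that forces an item score of 0
#'   regardless of performance — 1 error for Jumping Jacks and Pylon Obstacle
#'   Course (errors are rare on those tasks), 2 for Modified Shuttle Run, 3
#'   for Ins and Outs, and 5 for Backwards Tandem Walking (where errors are
#'   common).
#' * `cap_by_errors`: for error counts below `zero_score_at`, the maximum
#'   attainable score. With one error the cap is 3 for Backwards Tandem
#'   Walking, 2 for Ins and Outs and 1 for Modified Shuttle Run. Intermediate
#'   Backwards Tandem caps fall by one score point per additional error
#'   (floored at 1), and Ins and Outs caps at 1 with two errors; both choices
#'   are monotone and consistent with the published anchors.
#'
#' Standing Long Jump is scored 0 only when no trial has a valid two-foot
#' take-off and landing; its recorded error count affects normative
#' derivation (error-free filtering) but not scoring, so its rule is the
#' identity cap.
#'
#' @return Named list of `cca_error_rule` objects, one per task. Each holds
#'   `task_id`, `zero_score_at`, and `caps` (vector indexed by error count
#'   starting at 0; `caps[1]` is always 4).
#' @examples
#' rules <- cca_error_rules()
#' rules$backwards_tandem
#' @export
cca_error_rules <- function() {
  list(
    jumping_jacks = new_error_rule("jumping_jacks", 1L, 4L),
    pylon_obstacle = new_error_rule("pylon_obstacle", 1L, 4L),
    backwards_tandem = new_error_rule(
      "backwards_tandem", 5L, c(4L, 3L, 2L, 1L, 1L)
    ),
    shuttle_run = new_error_rule("shuttle_run", 2L, c(4L, 1L)),
    ins_and_outs = new_error_rule("ins_and_outs", 3L, c(4L, 2L, 1L)),
    long_jump = new_error_rule("long_jump", Inf, 4L)
  )
}

#' @export
print.cca_error_rule <- function(x, ...) {
  cat("<cca_error_rule>", x$task_id, "\n")
  if (is.finite(x$zero_score_at)) {
    cat("  score 0 at >=", x$zero_score_at, "error(s)\n")
  } else {
    cat("  errors do not modify the score\n")
  }
  caps <- x$caps
  cat(
    "  caps by error count:",
    paste(sprintf("%d->%d", seq_along(caps) - 1L, caps), collapse = " "),
    "\n"
  )
  invisible(x)
}

# map age in years to the instrument's age bands
age_band <- function(age) {
  ifelse(age <= 12, "9-12", "13-18")
}
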