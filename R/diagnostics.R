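#' Item difficulty and distribution diagnostics
#'
#' Computes the distributional statistics used to judge whether an item's
#' response scale fits the population: mean and SD of the item scores,
#' adjusted Fisher-Pearson skewness, and the percentage of participants at
#' the scale maximum. On the legacy 0-3 scale an item with mean score below
#' 2.0 is flagged `too_difficult` (the acceptability criterion was a mean of
#' at least 2.0 out of 3.0). On either scale, a heavy concentration at the
#' maximum (`pct_at_max` above `ceiling_pct`) or strong negative skew
#' (below `skew_bound`) flags a `ceiling_effect` — perfect scores in a
#' healthy cohort that would mask post-injury decline. An item with neither
#' flag is `acceptable`.
#'
#' @param scores Integer item scores in `0:scale_max`.
#' @param scale_max 3 (legacy 4-point scale) or 4 (final 5-point scale).
#' @param task_id Optional label carried into the output.
#' @param ceiling_pct Percentage at the maximum above which a ceiling effect
#'   is flagged (default 15).
#' @param skew_bound Skewness below which a ceiling effect is flagged
#'   (default -0.5).
#' @param difficulty_mean Mean-score floor for the 0-3 acceptability
#'   criterion (default 2.0).
#' @param pct_any_error Optional error prevalence (%) carried into the
#'   output for reporting.
#' @return One-row tibble: `task_id`, `n`, `mean_score`, `sd_score`,
#'   `skewness`, `pct_at_max`, `pct_any_error`, logical `too_difficult`,
#'   `ceiling_effect`, `acceptable`.
#' @examples
#' item_diagnostics(c(4, 4, 4, 3, 4, 4, 2, 4), scale_max = 4)
#' @export
item_diagnostics <- function(scores, scale_max = 4, task_id = NA_character_,
                             ceiling_pct = 15, skew_bound = -0.5,
                             difficulty_mean = 2.0,
                             pct_any_error = NA_real_) {
  if (length(scores) == 0 || all(is.na(scores))) {
    rlang::abort("No scores supplied.", class = "ccakit_diagnostics_error")
  }
  scores <- scores[!is.na(scores)]
  if (any(scores < 0 | scores > scale_max)) {
    rlang::abort(
      paste0("Scores must lie in [0, ", scale_max, "]."),
      class = "ccakit_input_error"
    )
  }
  n <- length(scores)
  m <- mean(scores)
  s <- stats::sd(scores)
  skew <- skewness_adjusted(scores)
  pct_max <- 100 * mean(scores == scale_max)
  too_difficult <- (scale_max == 3) && (m < difficulty_mean)
  ceiling <- (pct_max > ceiling_pct) ||
    (is.finite(skew) && skew < skew_bound)
  # an item cannot be both at the ceiling and too hard on one evaluation
  if (too_difficult) ceiling <- FALSE
  tibble::tibble(
    task_id = task_id, n = n, mean_score = m, sd_score = s,
    skewness = skew, pct_at_max = pct_max, pct_any_error = pct_any_error,
    too_difficult = too_difficult, ceiling_effect = ceiling,
    acceptable = !too_difficult && !ceiling
  )
}

# adjusted Fisher-Pearson standardized moment coefficient
skewness_adjusted <- function(x) {
  n <- length(x)
  if (n < 3) {
    return(NA_real_)
  }
  m <- mean(x)
  m2 <- sum((x - m)^2) / n
  if (m2 == 0) {
    return(NA_real_)
  }
  g1 <- (sum((x - m)^3) / n) / m2^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

#' Error prevalence for a task, with an error-rule recommendation
#'
#' The share of participants committing at least one error on a task guided
#' how its error rule was structured: where fewer than 5% of a healthy
#' normative cohort commit an error, a single error is strong evidence of
#' impaired performance and the score is automatically 0 (`auto_zero`);
#' where errors are common, graded caps preserve information
#' (`graded_caps`).
#'
#' @param sample Tibble of athlete records.
#' @param task Task id.
#' @param auto_zero_pct Prevalence boundary (default 5).
#' @return One-row tibble: `task_id`, `n`, `pct_any_error`,
#'   `recommended_rule`.
#' @export
error_prevalence <- function(sample, task, auto_zero_pct = 5) {
  task_info(task)
  if (nrow(sample) == 0) {
    rlang::abort("`sample` is empty.", class = "ccakit_diagnostics_error")
  }
  errs <- sample[[paste0(task, "_errors")]]
  pct <- 100 * mean(errs >= 1)
  tibble::tibble(
    task_id = task, n = nrow(sample), pct_any_error = pct,
    recommended_rule = ifelse(pct < auto_zero_pct, "auto_zero", "graded_caps")
  )
}

#' Diagnose every item of a scored sample
#'
#' @param scores Output of [score_sample()].
#' @param sample The raw sample the scores came from (for error
#'   prevalences); optional.
#' @param scale_max Scale maximum (default 4).
#' @param ... Passed to [item_diagnostics()].
#' @return Tibble with one diagnostics row per task.
#' @export
diagnose_items <- function(scores, sample = NULL, scale_max = 4, ...) {
  dplyr::bind_rows(lapply(cca_task_ids(), function(task) {
    pct_err <- if (!is.null(sample)) {
      error_prevalence(sample, task)$pct_any_error
    } else {
      NA_real_
    }
    item_diagnostics(
      scores[[paste0("score_", task)]],
      scale_max = scale_max, task_id = task,
      pct_any_error = pct_err, ...
    )
  }))
}

#' Histogram of item scores per task
#'
#' @param scores Output of [score_sample()].
#' @param scale_max Scale maximum (default 4).
#' @return A ggplot object, faceted by task.
#' @export
plot_score_distribution <- function(scores, scale_max = 4) {
  long <- tidyr::pivot_longer(
    scores,
    cols = dplyr::starts_with("score_"),
    names_to = "task_id", names_prefix = "score_",
    values_to = "score"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_bar(fill = "steelblue") +
    ggplot2::facet_wrap(~task_id) +
    ggplot2::scale_x_continuous(breaks = 0:scale_max) +
    ggplot2::labs(x = "Item score", y = "Participants") +
    ggplot2::theme_minimal()
}
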