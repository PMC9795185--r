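#' Single-measure test-retest intraclass correlation
#'
#' Estimates the single-measure ICC from paired measurements. The default is
#' the two-way random-effects, absolute-agreement form (often written
#' ICC(A,1) or ICC(2,1)), appropriate when the assessors at the two sessions
#' differ: the occasion/assessor variance counts against agreement. A
#' one-way random-effects form (ICC(1)) is available via `model`.
#'
#' Mean squares are computed directly from the paired data (rows = subjects,
#' columns = sessions): with `n` subjects and `k = 2` sessions,
#' \deqn{ICC(A,1) = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' where \eqn{MS_R}, \eqn{MS_C}, \eqn{MS_E} are the subject, session and
#' residual mean squares. The 95% confidence interval uses the F-based
#' approximation with Satterthwaite degrees of freedom. Negative estimates
#' (worse-than-chance agreement) are returned as computed.
#'
#' @param t1,t2 Numeric vectors of the session-1 and session-2 measurements,
#'   matched by position.
#' @param model `"two_way"` (absolute agreement, default) or `"one_way"`.
#' @param conf_level Confidence level (default 0.95).
#' @param min_n Minimum number of complete pairs (default 4).
#' @param subgroup Label used in error messages.
#' @return List with `icc`, `ci_lower`, `ci_upper`, `n_pairs`, `model`.
#' @examples
#' set.seed(1)
#' subject <- rnorm(60)
#' icc_single(subject + rnorm(60, sd = 0.5), subject + rnorm(60, sd = 0.5))
#' @export
icc_single <- function(t1, t2, model = c("two_way", "one_way"),
                       conf_level = 0.95, min_n = 4, subgroup = "all") {
  model <- match.arg(model)
  keep <- stats::complete.cases(t1, t2)
  t1 <- t1[keep]
  t2 <- t2[keep]
  n <- length(t1)
  if (n < min_n) {
    rlang::abort(
      paste0(
        "Subgroup '", subgroup, "': ", n, " complete pair(s); at least ",
        min_n, " required for a reliability estimate."
      ),
      class = "ccakit_reliability_error"
    )
  }
  if (!all(is.finite(t1)) || !all(is.finite(t2))) {
    rlang::abort("Measurements must be finite.", class = "ccakit_input_error")
  }
  k <- 2
  x <- cbind(t1, t2)
  gm <- mean(x)
  row_means <- rowMeans(x)
  col_means <- colMeans(x)
  ssr <- k * sum((row_means - gm)^2)
  ssc <- n * sum((col_means - gm)^2)
  sst <- sum((x - gm)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  alpha <- 1 - conf_level
  if (model == "one_way") {
    msw <- (sse + ssc) / (n * (k - 1))
    icc <- (msr - msw) / (msr + (k - 1) * msw)
    if (msw <= 0) {
      return(list(
        icc = 1, ci_lower = 1, ci_upper = 1, n_pairs = n, model = model
      ))
    }
    fobs <- msr / msw
    fl <- fobs / stats::qf(1 - alpha / 2, n - 1, n * (k - 1))
    fu <- fobs * stats::qf(1 - alpha / 2, n * (k - 1), n - 1)
    return(list(
      icc = icc,
      ci_lower = (fl - 1) / (fl + k - 1),
      ci_upper = (fu - 1) / (fu + k - 1),
      n_pairs = n, model = model
    ))
  }
  denom <- msr + (k - 1) * mse + (k / n) * (msc - mse)
  if (denom <= 0) {
    # all variance components vanish: constant data, agreement undefined
    rlang::abort("Paired values have no variance; ICC is undefined.",
      class = "ccakit_reliability_error"
    )
  }
  icc <- (msr - mse) / denom
  if (mse <= 0 && msc <= 0) {
    # exact agreement: no occasion noise, interval collapses
    return(list(
      icc = icc, ci_lower = icc, ci_upper = icc, n_pairs = n, model = model
    ))
  }
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  fstar1 <- stats::qf(1 - alpha / 2, n - 1, v)
  lower <- n * (msr - fstar1 * mse) /
    (fstar1 * (k * msc + (k * n - k - n) * mse) + n * msr)
  fstar2 <- stats::qf(1 - alpha / 2, v, n - 1)
  upper <- n * (fstar2 * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * fstar2 * msr)
  if (!is.finite(lower)) lower <- -1
  if (!is.finite(upper)) upper <- 1
  list(
    icc = icc, ci_lower = min(lower, icc), ci_upper = max(upper, icc),
    n_pairs = n, model = model
  )
}

#' Classify test-retest stability from an ICC
#'
#' Applies the three-band rule: ICC below 0.60 denotes unstable reliability,
#' 0.60 to 0.70 (inclusive at both ends) marginal reliability, and above
#' 0.70 stable test-retest reliability.
#'
#' @param icc Numeric vector of ICC estimates (may be negative).
#' @param unstable_below,stable_above Band boundaries (defaults 0.60, 0.70).
#' @return Character vector: `"unstable"`, `"marginal"` or `"stable"`.
#' @examples
#' classify_reliability(c(0.83, 0.65, -0.34))
#' @export
classify_reliability <- function(icc, unstable_below = 0.60,
                                 stable_above = 0.70) {
  if (any(!is.finite(icc))) {
    rlang::abort("`icc` must be finite.", class = "ccakit_input_error")
  }
  ifelse(icc < unstable_below, "unstable",
    ifelse(icc > stable_above, "stable", "marginal")
  )
}

# interval band used throughout: up to 12 months inclusive, else 12-24
interval_band <- function(interval_months) {
  ifelse(interval_months <= 12, "0-12", "12-24")
}

#' Test-retest reliability by task and subgroup
#'
#' Reshapes a paired sample (two rows per participant, sessions `"t1"` and
#' `"t2"`) and estimates the single-measure ICC with its 95% CI for each
#' task, for the whole group and within each requested subgroup: retest
#' interval band (0-12 vs 12-24 months), age band (9-12 vs 13-18 years) and
#' sex. Reliability is computed on the raw measures (seconds, repetitions,
#' metres). Subgroups with fewer than `min_n` pairs are reported with
#' `estimated = FALSE` and no estimate rather than dropped.
#'
#' @param pairs Paired sample from [simulate_retest_pairs()] or
#'   [read_retest_csv()].
#' @param stratifiers Subset of `c("interval", "age_band", "sex")`.
#' @param tasks Task ids (default all six).
#' @param model,conf_level,min_n Passed to [icc_single()].
#' @return Tibble with one row per task x subgroup: `task_id`,
#'   `subgroup_var`, `subgroup`, `n_pairs`, `mean_t1`, `sd_t1`, `mean_t2`,
#'   `sd_t2`, `icc`, `ci_lower`, `ci_upper`, `classification`, `estimated`.
#' @export
subgroup_reliability <- function(pairs,
                                 stratifiers = c("interval", "age_band", "sex"),
                                 tasks = cca_task_ids(),
                                 model = "two_way",
                                 conf_level = 0.95,
                                 min_n = 4) {
  stratifiers <- match.arg(stratifiers, several.ok = TRUE)
  required <- c("participant_id", "session", "age", "sex")
  if ("interval" %in% stratifiers) required <- c(required, "interval_months")
  missing_cols <- setdiff(required, names(pairs))
  if (length(missing_cols) > 0) {
    rlang::abort(
      paste0(
        "Paired sample is missing column(s): ",
        paste(missing_cols, collapse = ", ")
      ),
      class = "ccakit_schema_error"
    )
  }
  t1 <- pairs[pairs$session == "t1", ]
  t2 <- pairs[pairs$session == "t2", ]
  t2 <- t2[match(t1$participant_id, t2$participant_id), ]
  membership <- list(all = list(all = rep(TRUE, nrow(t1))))
  if ("interval" %in% stratifiers) {
    band <- interval_band(t1$interval_months)
    membership$interval <- list(`0-12` = band == "0-12", `12-24` = band == "12-24")
  }
  if ("age_band" %in% stratifiers) {
    ab <- age_band(t1$age)
    membership$age_band <- list(`9-12` = ab == "9-12", `13-18` = ab == "13-18")
  }
  if ("sex" %in% stratifiers) {
    membership$sex <- list(
      male = t1$sex == "male", female = t1$sex == "female"
    )
  }
  rows <- list()
  for (task in tasks) {
    col <- paste0(task, "_raw")
    for (var in names(membership)) {
      for (level in names(membership[[var]])) {
        sel <- membership[[var]][[level]]
        y1 <- t1[[col]][sel]
        y2 <- t2[[col]][sel]
        n_sel <- sum(stats::complete.cases(y1, y2))
        est <- tryCatch(
          icc_single(y1, y2,
            model = model, conf_level = conf_level,
            min_n = min_n, subgroup = paste(var, level)
          ),
          ccakit_reliability_error = function(e) NULL
        )
        rows[[length(rows) + 1]] <- tibble::tibble(
          task_id = task, subgroup_var = var, subgroup = level,
          n_pairs = n_sel,
          mean_t1 = if (n_sel) mean(y1, na.rm = TRUE) else NA_real_,
          sd_t1 = if (n_sel > 1) stats::sd(y1, na.rm = TRUE) else NA_real_,
          mean_t2 = if (n_sel) mean(y2, na.rm = TRUE) else NA_real_,
          sd_t2 = if (n_sel > 1) stats::sd(y2, na.rm = TRUE) else NA_real_,
          icc = if (is.null(est)) NA_real_ else est$icc,
          ci_lower = if (is.null(est)) NA_real_ else est$ci_lower,
          ci_upper = if (is.null(est)) NA_real_ else est$ci_upper,
          classification = if (is.null(est)) {
            NA_character_
          } else {
            classify_reliability(est$icc)
          },
          estimated = !is.null(est)
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Partition tasks into outcome and exertion items
#'
#' A task qualifies for the longitudinal outcome set when its whole-group
#' single-measure ICC exceeds the stability target (0.70) in the chosen
#' retest-interval band; the remaining tasks are retained as standalone
#' exertion items.
#'
#' @param results Either a reliability table from [subgroup_reliability()]
#'   (rows for `subgroup_var == "interval"` are used) or a named numeric
#'   vector of per-task ICCs for the chosen interval.
#' @param interval Interval band, default `"0-12"` months.
#' @param threshold Stability target (default 0.70, strict inequality).
#' @return List with character vectors `outcome` and `exertion`.
#' @examples
#' select_outcome_items(c(
#'   jumping_jacks = 0.56, pylon_obstacle = 0.38, backwards_tandem = 0.83,
#'   shuttle_run = 0.48, ins_and_outs = 0.73, long_jump = 0.81
#' ))
#' @export
select_outcome_items <- function(results, interval = "0-12",
                                 threshold = 0.70) {
  if (is.data.frame(results)) {
    sub <- results[
      results$subgroup_var == "interval" & results$subgroup == interval,
    ]
    icc <- stats::setNames(sub$icc, sub$task_id)
  } else {
    icc <- results
  }
  missing_tasks <- setdiff(cca_task_ids(), names(icc))
  if (length(missing_tasks) > 0 || any(is.na(icc[cca_task_ids()]))) {
    rlang::abort(
      paste0(
        "Reliability results must cover all six tasks for interval '",
        interval, "'; missing or unestimated: ",
        paste(
          union(missing_tasks, names(icc)[is.na(icc)]),
          collapse = ", "
        ), "."
      ),
      class = "ccakit_selection_error"
    )
  }
  icc <- icc[cca_task_ids()]
  outcome <- names(icc)[icc > threshold]
  if (length(outcome) == 0) {
    rlang::warn("No task exceeds the stability target; outcome set is empty.")
  }
  list(outcome = outcome, exertion = setdiff(cca_task_ids(), outcome))
}

#' Published whole-group reliability estimates for the CCA tasks
#'
#' Whole-group single-measure test-retest ICCs reported for the instrument
#' by retest-interval band, shipped as a plain-text fixture. These are the
#' reference values that motivated the outcome/exertion partition: in the
#' 0-12-month band only Backwards Tandem Walking, Ins and Outs and Standing
#' Long Jump exceed the 0.70 stability target.
#'
#' @return Tibble with `task_id`, `interval`, `n_pairs`, `icc`.
#' @export
cca_published_reliability <- function() {
  path <- system.file("extdata", "cca_published_icc.csv", package = "ccakit")
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
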