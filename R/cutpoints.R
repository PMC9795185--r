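#' Keep only records that performed a task without error
#'
#' Cut points are derived exclusively from error-free performances so that
#' speed or distance is never rewarded at the expense of accuracy. For the
#' standing long jump a record is error-free when it has zero recorded
#' errors and at least one valid-landing trial.
#'
#' @param sample Tibble of athlete records.
#' @param task Task id.
#' @return The error-free subsample (same columns).
#' @export
filter_error_free <- function(sample, task) {
  task_info(task)
  if (nrow(sample) == 0) {
    rlang::abort("`sample` is empty.", class = "ccakit_derivation_error")
  }
  keep <- sample[[paste0(task, "_errors")]] == 0
  if (task == "long_jump") {
    any_valid <- sample$long_jump_v1 | sample$long_jump_v2 | sample$long_jump_v3
    keep <- keep & any_valid
  }
  out <- sample[which(keep), ]
  if (nrow(out) == 0) {
    rlang::abort(
      paste0(
        "No error-free records for task '", task,
        "'; a larger normative sample is needed to derive cut points."
      ),
      class = "ccakit_derivation_error"
    )
  }
  out
}

# derivation value per record: the raw measure, or for the long jump the
# best distance among valid trials (matching how the task is scored)
task_values <- function(sample, task) {
  if (task == "long_jump") {
    d <- as.matrix(sample[, paste0("long_jump_d", 1:3)])
    v <- as.matrix(sample[, paste0("long_jump_v", 1:3)])
    d[!v] <- -Inf
    vals <- apply(d, 1, max)
    vals[!is.finite(vals)] <- NA_real_
    vals
  } else {
    sample[[paste0(task, "_raw")]]
  }
}

#' Derive mean ± SD cut points (legacy 4-point method)
#'
#' The single cut point sits one standard deviation from the mean on the
#' better side of the distribution, so the top category requires performing
#' at least 1 SD better than average: at `mean - 1 SD` for lower-better
#' (timed) tasks and `mean + 1 SD` for higher-better tasks. With two cut
#' points the second sits at 2 SDs, twice as far from the mean.
#'
#' @param values Error-free raw values (>= 2).
#' @param n_cuts 1 or 2.
#' @param direction `"lower_better"` or `"higher_better"`.
#' @return Ascending numeric cut points with attribute `degenerate` set when
#'   the values have zero spread.
#' @examples
#' derive_mean_sd_thresholds(c(10, 12, 14), 1, "lower_better") # 12 - 2 = 10
#' @export
derive_mean_sd_thresholds <- function(values, n_cuts = 1,
                                      direction = c(
                                        "lower_better", "higher_better"
                                      )) {
  direction <- match.arg(direction)
  if (!n_cuts %in% c(1L, 2L)) {
    rlang::abort("`n_cuts` must be 1 or 2.", class = "ccakit_config_error")
  }
  values <- values[!is.na(values)]
  if (length(values) < 2) {
    rlang::abort("At least 2 error-free values are needed.",
      class = "ccakit_derivation_error"
    )
  }
  m <- mean(values)
  s <- stats::sd(values)
  sign <- if (direction == "lower_better") -1 else 1
  cuts <- m + sign * s * seq_len(n_cuts)
  cuts <- sort(cuts)
  if (s == 0) {
    rlang::warn("Zero spread in derivation values; cut points are degenerate.")
  }
  structure(cuts, degenerate = (s == 0))
}

#' Derive quartile cut points (final 5-point method)
#'
#' The three cut points are the 25th, 50th and 75th percentiles of the
#' error-free raw-value distribution (linear interpolation between order
#' statistics, the type-7 quantile convention, for reproducibility). Fed to
#' [bin_score()], they partition the derivation sample into four
#' approximately equal-occupancy bins, with the best quartile (fastest
#' times, longest distances, most repetitions) mapping to bin 4.
#'
#' @param values Error-free raw values (>= 4).
#' @param direction `"lower_better"` or `"higher_better"` (recorded for
#'   validation; cut points are returned ascending either way).
#' @return Ascending numeric cut points `(Q1, Q2, Q3)` with attribute
#'   `degenerate` when tied.
#' @examples
#' derive_quartile_thresholds(1:8, "higher_better") # 2.75 4.50 6.25
#' @export
derive_quartile_thresholds <- function(values,
                                       direction = c(
                                         "lower_better", "higher_better"
                                       )) {
  direction <- match.arg(direction)
  values <- values[!is.na(values)]
  if (length(values) < 4) {
    rlang::abort("At least 4 error-free values are needed for quartiles.",
      class = "ccakit_derivation_error"
    )
  }
  cuts <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = 7))
  degenerate <- any(duplicated(cuts))
  if (degenerate) {
    rlang::warn("Tied quartiles in derivation values; form is degenerate.")
  }
  structure(cuts, degenerate = degenerate)
}

#' Summarise a normative sample per task (and stratum)
#'
#' @param sample Tibble of athlete records.
#' @param stratify Split by age band x sex when `TRUE`.
#' @return Tibble with one row per task (x stratum): total and error-free
#'   counts, mean, SD and quartiles of the error-free derivation values.
#' @export
normative_summary <- function(sample, stratify = FALSE) {
  groups <- if (stratify) {
    split(sample, stratum_key(sample$age, sample$sex))
  } else {
    list(pooled = sample)
  }
  rows <- lapply(names(groups), function(key) {
    g <- groups[[key]]
    dplyr::bind_rows(lapply(cca_task_ids(), function(task) {
      ef <- tryCatch(filter_error_free(g, task), error = function(e) NULL)
      vals <- if (is.null(ef)) numeric(0) else task_values(ef, task)
      q <- if (length(vals) >= 4) {
        stats::quantile(vals, c(.25, .5, .75), type = 7)
      } else {
        rep(NA_real_, 3)
      }
      tibble::tibble(
        task_id = task, stratum = key,
        n_total = nrow(g), n_error_free = length(vals),
        mean = if (length(vals)) mean(vals) else NA_real_,
        sd = if (length(vals) > 1) stats::sd(vals) else NA_real_,
        q1 = q[[1]], q2 = q[[2]], q3 = q[[3]]
      )
    }))
  })
  dplyr::bind_rows(rows)
}

#' Build scoring forms from a normative sample
#'
#' For each task the sample is first reduced to error-free performances,
#' then cut points are derived with the chosen method. With
#' `stratify = TRUE` separate forms are built for the four age-band x sex
#' strata (female/male children 9-12, female/male adolescents 13-18);
#' otherwise one pooled form is returned. Each form carries provenance: the
#' per-task error-free n, the stratum, and the derivation seed if supplied.
#'
#' @param sample Tibble of athlete records.
#' @param method `"quartile_5pt"` (default, 3 cut points) or `"mean_sd_4pt"`.
#' @param stratify Build four stratified forms instead of one pooled form.
#' @param n_cuts Number of cut points for the mean±SD method (1 or 2).
#' @param min_n Minimum error-free records required per task (and stratum).
#' @param sample_id,seed Provenance fields stored on the forms.
#' @return A `cca_scoring_form` (pooled) or a named list of four forms with
#'   names like `"female_9-12"`.
#' @export
build_scoring_forms <- function(sample,
                                method = c("quartile_5pt", "mean_sd_4pt"),
                                stratify = FALSE,
                                n_cuts = 2,
                                min_n = 30,
                                sample_id = "normative",
                                seed = NULL) {
  method <- match.arg(method)
  build_one <- function(records, stratum, key) {
    thresholds <- list()
    n_used <- integer(0)
    degenerate <- logical(0)
    for (task in cca_task_ids()) {
      info <- task_info(task)
      ef <- tryCatch(filter_error_free(records, task),
        error = function(e) records[0, ]
      )
      vals <- task_values(ef, task)
      vals <- vals[!is.na(vals)]
      if (length(vals) < min_n) {
        rlang::abort(
          paste0(
            "Stratum '", key, "', task '", task, "': only ", length(vals),
            " error-free record(s); ", min_n, " required."
          ),
          class = "ccakit_derivation_error"
        )
      }
      cuts <- if (method == "quartile_5pt") {
        derive_quartile_thresholds(vals, info$direction)
      } else {
        derive_mean_sd_thresholds(vals, n_cuts, info$direction)
      }
      thresholds[[task]] <- as.numeric(cuts)
      n_used[task] <- length(vals)
      degenerate[task] <- isTRUE(attr(cuts, "degenerate"))
    }
    scoring_form(
      thresholds = thresholds, method = method, stratum = stratum,
      provenance = list(
        sample_id = sample_id, n_used = as.list(n_used), seed = seed
      ),
      degenerate = degenerate
    )
  }
  if (!stratify) {
    return(build_one(sample, "pooled", "pooled"))
  }
  strata <- expand.grid(
    sex = c("female", "male"), band = c("9-12", "13-18"),
    stringsAsFactors = FALSE
  )
  forms <- list()
  for (i in seq_len(nrow(strata))) {
    sex <- strata$sex[i]
    band <- strata$band[i]
    key <- paste(sex, band, sep = "_")
    records <- sample[sample$sex == sex & age_band(sample$age) == band, ]
    forms[[key]] <- build_one(
      records, list(age_band = band, sex = sex), key
    )
  }
  forms
}
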