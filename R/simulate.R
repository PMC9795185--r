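#' Default per-task simulation parameters
#'
#' Location/scale defaults approximate a healthy youth-athlete cohort:
#' roughly 23 jumping jacks (SD 2.6), 6.8 s pylon course (SD 0.75), 19 s
#' backwards tandem walk (SD 6), 18.7 s shuttle run (SD 1.6), 6.8 s ins and
#' outs (SD 1.5) and a 1.55 m standing long jump (SD 0.25) at the pooled
#' level. `location` is the child-female baseline; `age_effect` (adolescents
#' 13-18 vs children 9-12) and `sex_effect` (male vs female) shift the
#' location additively per stratum, in the direction of better performance
#' with age/male sex on speed and strength tasks. `error_rate` is the
#' expected Poisson error count per attempt, chosen so that the share of
#' participants committing at least one error matches typical task-specific
#' prevalences (rare for jumping jacks and the pylon course, common for the
#' backwards tandem walk).
#'
#' @return Named list of per-task parameter lists with fields `family`
#'   (`lognormal`, `count`, `truncnorm`), `location`, `scale`, `error_rate`,
#'   `age_effect`, `sex_effect`.
#' @export
cca_task_params <- function() {
  list(
    jumping_jacks = list(
      family = "count", location = 22.2, scale = 2.6,
      error_rate = 0.0182, age_effect = 1.5, sex_effect = 1.0
    ),
    pylon_obstacle = list(
      family = "lognormal", location = 7.2, scale = 0.75,
      error_rate = 0.0243, age_effect = -0.3, sex_effect = -0.55
    ),
    backwards_tandem = list(
      family = "lognormal", location = 20.5, scale = 6.0,
      error_rate = 0.805, age_effect = 0, sex_effect = -3.0
    ),
    shuttle_run = list(
      family = "lognormal", location = 19.0, scale = 1.6,
      error_rate = 0.1256, age_effect = 0, sex_effect = -0.6
    ),
    ins_and_outs = list(
      family = "lognormal", location = 7.35, scale = 1.5,
      error_rate = 0.2945, age_effect = -0.4, sex_effect = -0.7
    ),
    long_jump = list(
      family = "truncnorm", location = 1.42, scale = 0.25,
      error_rate = 0.02, age_effect = 0.15, sex_effect = 0.12
    )
  )
}

#' Simulation configuration
#'
#' Bundles and validates every knob of the synthetic-cohort generator. The
#' defaults emulate the normative study conditions: a cross-sectional sample
#' of 854 youth athletes aged 9-18, balanced sexes, task-specific error
#' processes, and a paired test-retest design with retest intervals spread
#' over 2 weeks to 24 months and per-task true single-measure reliabilities
#' matching published whole-group estimates.
#'
#' @param n Number of participants (>= 1).
#' @param age_range Integer ages are drawn uniformly from
#'   `age_range[1]:age_range[2]`.
#' @param sex_ratio Proportion male in `[0, 1]`.
#' @param tasks Per-task distribution parameters, see [cca_task_params()].
#' @param invalid_landing_rate Per-trial probability that a standing long
#'   jump landing is invalid.
#' @param retest List with `true_icc` (named per-task values in `(0, 1]`)
#'   and `interval_months` (range the retest interval is drawn from).
#' @param seed Integer seed; the single source of randomness. Per-task
#'   sub-streams are derived from it deterministically, so identical
#'   configurations yield identical samples.
#' @param id_prefix Prefix for generated participant ids.
#' @return A validated `cca_sim_config`.
#' @export
sim_config <- function(n = 854,
                       age_range = c(9L, 18L),
                       sex_ratio = 0.5,
                       tasks = cca_task_params(),
                       invalid_landing_rate = 0.036,
                       retest = list(
                         true_icc = c(
                           jumping_jacks = 0.56, pylon_obstacle = 0.38,
                           backwards_tandem = 0.83, shuttle_run = 0.48,
                           ins_and_outs = 0.73, long_jump = 0.81
                         ),
                         interval_months = c(0.5, 24)
                       ),
                       seed = 20221214L,
                       id_prefix = "P") {
  bad_field <- function(field, why) {
    rlang::abort(paste0("Invalid `", field, "`: ", why),
      class = "ccakit_config_error"
    )
  }
  if (length(n) != 1 || is.na(n) || n < 1 || n != floor(n)) {
    bad_field("n", "must be a single integer >= 1.")
  }
  if (length(age_range) != 2 || age_range[1] > age_range[2]) {
    bad_field("age_range", "must be an ascending pair of ages.")
  }
  if (sex_ratio < 0 || sex_ratio > 1) {
    bad_field("sex_ratio", "must lie in [0, 1].")
  }
  if (invalid_landing_rate < 0 || invalid_landing_rate > 1) {
    bad_field("invalid_landing_rate", "must lie in [0, 1].")
  }
  missing_tasks <- setdiff(cca_task_ids(), names(tasks))
  if (length(missing_tasks) > 0) {
    bad_field("tasks", paste0(
      "missing parameters for ", paste(missing_tasks, collapse = ", "), "."
    ))
  }
  for (task in cca_task_ids()) {
    p <- tasks[[task]]
    if (!is.numeric(p$scale) || p$scale <= 0) {
      bad_field(paste0("tasks$", task, "$scale"), "must be > 0.")
    }
    if (!is.numeric(p$error_rate) || p$error_rate < 0) {
      bad_field(paste0("tasks$", task, "$error_rate"), "must be >= 0.")
    }
    if (!is.numeric(p$location) || p$location <= 0) {
      bad_field(paste0("tasks$", task, "$location"), "must be > 0.")
    }
  }
  icc <- retest$true_icc
  if (any(is.na(icc)) || any(icc <= 0) || any(icc > 1)) {
    bad_field("retest$true_icc", "values must lie in (0, 1].")
  }
  if (length(seed) != 1 || is.na(seed) || seed != floor(seed)) {
    bad_field("seed", "must be a single integer.")
  }
  structure(
    list(
      n = as.integer(n), age_range = as.integer(age_range),
      sex_ratio = sex_ratio, tasks = tasks,
      invalid_landing_rate = invalid_landing_rate,
      retest = retest, seed = as.integer(seed), id_prefix = id_prefix
    ),
    class = "cca_sim_config"
  )
}

# run code under a deterministic sub-stream without clobbering the caller's
# RNG state; stream index keeps task draws independent of task order changes
with_stream <- function(seed, stream, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else {
    NULL
  }
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, globalenv())
    } else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed((seed + 104729L * stream) %% 2147483629L)
  force(code)
}

stream_index <- function(task) match(task, cca_task_ids())

stratum_location <- function(p, age, sex) {
  p$location +
    p$age_effect * (age_band(age) == "13-18") +
    p$sex_effect * (sex == "male")
}

# draw raw values for one task given per-record locations
draw_raw <- function(p, loc, n) {
  switch(p$family,
    lognormal = {
      cv2 <- (p$scale / loc)^2
      sdlog <- sqrt(log1p(cv2))
      meanlog <- log(loc) - sdlog^2 / 2
      stats::rlnorm(n, meanlog, sdlog)
    },
    count = pmax(0, round(stats::rnorm(n, loc, p$scale))),
    truncnorm = pmax(0.01, stats::rnorm(n, loc, p$scale)),
    rlang::abort(paste0("Unknown distribution family '", p$family, "'."),
      class = "ccakit_config_error"
    )
  )
}

simulate_demographics <- function(config) {
  with_stream(config$seed, 0L, {
    tibble::tibble(
      participant_id = sprintf(
        "%s%05d", config$id_prefix, seq_len(config$n)
      ),
      age = sample(config$age_range[1]:config$age_range[2],
        config$n,
        replace = TRUE
      ),
      sex = ifelse(stats::runif(config$n) < config$sex_ratio,
        "male", "female"
      )
    )
  })
}

#' Generate a normative cross-sectional sample
#'
#' Draws one session of raw performances and error counts per participant:
#' timed tasks from a lognormal (positive, right-skewed as typical of timed
#' motor tasks), jumping-jack repetitions as a rounded normal truncated at
#' zero, and long-jump distances as a truncated normal with three trials per
#' participant (a shared ability component plus trial noise) and Bernoulli
#' landing-validity flags. Error counts are independent Poisson draws with
#' task-specific rates.
#'
#' @param config A [sim_config()].
#' @return Tibble with one row per participant: `participant_id`, `age`,
#'   `sex`, `session` (`"t1"`), `<task>_raw` and `<task>_errors` columns for
#'   the five single-trial tasks, and `long_jump_d1..d3` / `long_jump_v1..v3`
#'   / `long_jump_errors` for the standing long jump.
#' @examples
#' sample <- simulate_normative_sample(sim_config(n = 50, seed = 1))
#' dplyr::glimpse(sample)
#' @export
simulate_normative_sample <- function(config) {
  stopifnot(inherits(config, "cca_sim_config"))
  out <- simulate_demographics(config)
  out$session <- "t1"
  n <- config$n
  for (task in cca_task_ids()) {
    p <- config$tasks[[task]]
    loc <- stratum_location(p, out$age, out$sex)
    if (task == "long_jump") {
      sims <- with_stream(config$seed, stream_index(task), {
        ability <- stats::rnorm(n, loc, p$scale * sqrt(0.8))
        trial_sd <- p$scale * sqrt(0.2)
        d <- vapply(1:3, function(j) {
          pmax(0.01, ability + stats::rnorm(n, 0, trial_sd))
        }, numeric(n))
        v <- matrix(
          stats::runif(3 * n) >= config$invalid_landing_rate,
          nrow = n
        )
        list(
          d = d, v = v,
          errors = stats::rpois(n, p$error_rate)
        )
      })
      out$long_jump_d1 <- sims$d[, 1]
      out$long_jump_d2 <- sims$d[, 2]
      out$long_jump_d3 <- sims$d[, 3]
      out$long_jump_v1 <- sims$v[, 1]
      out$long_jump_v2 <- sims$v[, 2]
      out$long_jump_v3 <- sims$v[, 3]
      out$long_jump_errors <- sims$errors
    } else {
      sims <- with_stream(config$seed, stream_index(task), {
        list(
          raw = draw_raw(p, loc, n),
          errors = stats::rpois(n, p$error_rate)
        )
      })
      out[[paste0(task, "_raw")]] <- sims$raw
      out[[paste0(task, "_errors")]] <- sims$errors
    }
  }
  out
}

#' Generate paired test-retest records
#'
#' Each participant's two sessions are drawn as subject effect plus occasion
#' noise on the natural measurement scale. The between-subject variance has
#' two parts — the age/sex stratum shifts of the cohort and a random subject
#' effect — and the subject effect is sized so that their sum is a fraction
#' `r` (the target reliability) of the total variance
#' `scale^2 + var(stratum shifts)`, with occasion noise supplying the
#' remaining `1 - r`. The cohort's single-measure ICC therefore equals `r`
#' exactly; if the stratum shifts alone exceed the requested between-subject
#' share the subject effect floors at zero with a warning. When the target
#' reliability is 1 the two sessions are identical. The long jump enters as
#' a single best-distance measure per session, matching how it is analysed.
#'
#' @param config A [sim_config()]; `config$retest$true_icc` supplies the
#'   per-task target reliabilities and `config$retest$interval_months` the
#'   range retest intervals are drawn from.
#' @param tasks Task ids to simulate (default all six).
#' @return Tibble with two rows per participant (`session` `"t1"`/`"t2"`):
#'   demographics, `interval_months`, and `<task>_raw` / `<task>_errors`
#'   columns.
#' @examples
#' pairs <- simulate_retest_pairs(sim_config(n = 30, seed = 2))
#' head(pairs)
#' @export
simulate_retest_pairs <- function(config, tasks = cca_task_ids()) {
  stopifnot(inherits(config, "cca_sim_config"))
  missing_icc <- setdiff(tasks, names(config$retest$true_icc))
  if (length(missing_icc) > 0) {
    rlang::abort(
      paste0(
        "Invalid `retest$true_icc`: no value for ",
        paste(missing_icc, collapse = ", "), "."
      ),
      class = "ccakit_config_error"
    )
  }
  demo <- simulate_demographics(config)
  n <- config$n
  ival <- config$retest$interval_months
  demo$interval_months <- with_stream(config$seed, 7L, {
    round(stats::runif(n, ival[1], ival[2]), 1)
  })
  t1 <- dplyr::mutate(demo, session = "t1")
  t2 <- dplyr::mutate(demo, session = "t2")
  for (task in tasks) {
    p <- config$tasks[[task]]
    r <- unname(config$retest$true_icc[[task]])
    loc <- stratum_location(p, demo$age, demo$sex)
    # age/sex stratum shifts are themselves between-subject variance; count
    # them toward the subject component so the cohort ICC targets r exactly
    v_demo <- sum((loc - mean(loc))^2) / n
    total_var <- p$scale^2 + v_demo
    subj_var <- r * total_var - v_demo
    if (subj_var < 0) {
      subj_var <- 0
      rlang::warn(paste0(
        "Task '", task, "': demographic heterogeneity alone exceeds the ",
        "requested true_icc; achieved reliability will be higher."
      ))
    }
    sims <- with_stream(config$seed, 100L + stream_index(task), {
      subject <- stats::rnorm(n, 0, sqrt(subj_var))
      noise_sd <- sqrt((1 - r) * total_var)
      e1 <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else numeric(n)
      e2 <- if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else numeric(n)
      list(
        y1 = pmax(0.01, loc + subject + e1),
        y2 = pmax(0.01, loc + subject + e2),
        err1 = stats::rpois(n, p$error_rate),
        err2 = stats::rpois(n, p$error_rate)
      )
    })
    t1[[paste0(task, "_raw")]] <- sims$y1
    t2[[paste0(task, "_raw")]] <- sims$y2
    t1[[paste0(task, "_errors")]] <- sims$err1
    t2[[paste0(task, "_errors")]] <- sims$err2
  }
  dplyr::arrange(
    dplyr::bind_rows(t1, t2),
    .data$participant_id, .data$session
  )
}
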