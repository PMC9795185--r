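# Independent oracles and fixture builders shared across tests.

# ICC(A,1) via stats::aov mean squares -> variance-components ratio;
# a separate route from the package's direct sums-of-squares formula.
oracle_icc_a1 <- function(t1, t2) {
  n <- length(t1)
  d <- data.frame(
    y = c(t1, t2),
    subj = factor(rep(seq_len(n), 2)),
    sess = factor(rep(1:2, each = n))
  )
  a <- stats::anova(stats::aov(y ~ subj + sess, data = d))
  msr <- a["subj", "Mean Sq"]
  msc <- a["sess", "Mean Sq"]
  mse <- a["Residuals", "Mean Sq"]
  var_subj <- (msr - mse) / 2
  var_sess <- (msc - mse) / n
  var_subj / (var_subj + var_sess + mse)
}

# Hand-encoded score table: what each task's error rule should produce for a
# given performance bin and error count, written down independently of
# apply_error_rule().
oracle_item_score <- function(task, bin, errors) {
  if (task %in% c("jumping_jacks", "pylon_obstacle")) {
    if (errors >= 1) 0L else bin
  } else if (task == "shuttle_run") {
    if (errors >= 2) 0L else if (errors == 1) min(bin, 1L) else bin
  } else if (task == "ins_and_outs") {
    if (errors >= 3) {
      0L
    } else if (errors == 2) {
      min(bin, 1L)
    } else if (errors == 1) {
      min(bin, 2L)
    } else {
      bin
    }
  } else if (task == "backwards_tandem") {
    if (errors >= 5) 0L else min(bin, max(1L, 4L - errors))
  } else {
    bin # long jump: errors do not modify the score
  }
}

# brute-force adjusted Fisher-Pearson skewness via explicit loops
oracle_skewness <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  s2 <- 0
  s3 <- 0
  for (xi in x) {
    s2 <- s2 + (xi - m)^2
    s3 <- s3 + (xi - m)^3
  }
  g1 <- (s3 / n) / (s2 / n)^1.5
  g1 * sqrt(n * (n - 1)) / (n - 2)
}

# one-row athlete record with sensible defaults, overridable per task
make_record <- function(..., errors = list()) {
  rec <- tibble::tibble(
    participant_id = "X0001", age = 12L, sex = "female", session = "t1",
    jumping_jacks_raw = 22, jumping_jacks_errors = 0L,
    pylon_obstacle_raw = 7, pylon_obstacle_errors = 0L,
    backwards_tandem_raw = 19, backwards_tandem_errors = 0L,
    shuttle_run_raw = 18.5, shuttle_run_errors = 0L,
    ins_and_outs_raw = 7, ins_and_outs_errors = 0L,
    long_jump_d1 = 1.2, long_jump_d2 = 1.3, long_jump_d3 = 1.4,
    long_jump_v1 = TRUE, long_jump_v2 = TRUE, long_jump_v3 = TRUE,
    long_jump_errors = 0L
  )
  overrides <- list(...)
  for (nm in names(overrides)) rec[[nm]] <- overrides[[nm]]
  for (nm in names(errors)) rec[[paste0(nm, "_errors")]] <- errors[[nm]]
  rec
}

# fixed hand-written form with 3 cut points per task (ascending, raw units)
test_form <- function() {
  scoring_form(
    thresholds = list(
      jumping_jacks = c(20, 23, 26),
      pylon_obstacle = c(6, 7, 8),
      backwards_tandem = c(14, 19, 24),
      shuttle_run = c(17, 18.5, 20),
      ins_and_outs = c(6, 7, 8),
      long_jump = c(1.0, 1.25, 1.5)
    ),
    method = "quartile_5pt"
  )
}

# one raw value strictly inside each of the four bins, best bin first
bin_representatives <- function(thresholds, direction) {
  gap <- min(diff(thresholds)) / 2
  mids <- c(
    thresholds[1] - gap,
    (thresholds[1] + thresholds[2]) / 2,
    (thresholds[2] + thresholds[3]) / 2,
    thresholds[3] + gap
  )
  if (direction == "lower_better") mids else rev(mids)
}

# a config whose error processes are switched off (for derivation tests)
error_free_config <- function(n, seed, ...) {
  tasks <- cca_task_params()
  for (t in names(tasks)) tasks[[t]]$error_rate <- 0
  sim_config(
    n = n, seed = seed, tasks = tasks, invalid_landing_rate = 0, ...
  )
}

flat_icc <- function(value) {
  stats::setNames(rep(value, 6), cca_task_ids())
}
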