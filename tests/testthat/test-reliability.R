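test_that("icc_single matches the independent ANOVA oracle", {
  set.seed(99)
  for (rep in 1:100) {
    n <- sample(4:50, 1)
    subject <- rnorm(n, sd = runif(1, 0.5, 3))
    t1 <- 10 + subject + rnorm(n, sd = runif(1, 0.2, 2))
    t2 <- 10 + subject + rnorm(n, sd = runif(1, 0.2, 2))
    expect_equal(
      icc_single(t1, t2)$icc, oracle_icc_a1(t1, t2),
      tolerance = 1e-10
    )
  }
})

test_that("perfect agreement gives ICC exactly 1", {
  est <- icc_single(c(12, 15, 19, 23, 31), c(12, 15, 19, 23, 31))
  expect_equal(est$icc, 1)
  expect_equal(est$ci_lower, 1)
  expect_equal(est$ci_upper, 1)
})

test_that("independent sessions give ICC near zero", {
  set.seed(7)
  est <- icc_single(rnorm(1000), rnorm(1000))
  expect_lt(abs(est$icc), 0.1)
})

test_that("the ICC is invariant to rescaling the raw measure", {
  set.seed(3)
  b <- rnorm(80)
  t1 <- 20 + b + rnorm(80, sd = 0.5)
  t2 <- 20 + b + rnorm(80, sd = 0.5)
  expect_equal(
    icc_single(t1, t2)$icc, icc_single(t1 * 37.5, t2 * 37.5)$icc,
    tolerance = 1e-12
  )
})

test_that("one-way and two-way models agree when no session effect exists", {
  set.seed(15)
  b <- rnorm(2000, sd = sqrt(0.7))
  t1 <- 5 + b + rnorm(2000, sd = sqrt(0.3))
  t2 <- 5 + b + rnorm(2000, sd = sqrt(0.3))
  two <- icc_single(t1, t2, model = "two_way")$icc
  one <- icc_single(t1, t2, model = "one_way")$icc
  expect_lt(abs(two - one), 0.02)
  expect_lt(abs(two - 0.7), 0.05)
})

test_that("too few pairs raise a subgroup-addressed reliability error", {
  expect_error(
    icc_single(1:3, 2:4, subgroup = "age_band 9-12"),
    regexp = "9-12",
    class = "ccakit_reliability_error"
  )
})

test_that("stability bands apply the published three-band rule", {
  expect_equal(classify_reliability(0.83), "stable")
  expect_equal(classify_reliability(0.65), "marginal")
  expect_equal(classify_reliability(-0.34), "unstable")
  # boundaries are inclusive to the marginal band
  expect_equal(classify_reliability(c(0.60, 0.70)), c("marginal", "marginal"))
  expect_equal(classify_reliability(0.5999), "unstable")
  expect_equal(classify_reliability(0.7001), "stable")
})

test_that("subgroup reliability covers every task-by-subgroup cell", {
  cfg <- sim_config(n = 80, seed = 55)
  pairs <- simulate_retest_pairs(cfg)
  res <- subgroup_reliability(pairs)
  # 1 whole-group + 2 interval + 2 age + 2 sex rows per task
  expect_equal(nrow(res), 6 * 7)
  expect_true(all(table(res$task_id) == 7))
  est <- res[res$estimated, ]
  expect_true(all(est$ci_lower <= est$icc & est$icc <= est$ci_upper))
  expect_true(all(
    est$classification %in% c("unstable", "marginal", "stable")
  ))
})

test_that("undersized subgroups are flagged instead of estimated", {
  cfg <- sim_config(n = 40, seed = 77, age_range = c(9, 12))
  pairs <- simulate_retest_pairs(cfg)
  # only 3 adolescent pairs: inject them explicitly
  pairs$age[pairs$participant_id %in% c("P00001", "P00002", "P00003")] <- 15L
  res <- subgroup_reliability(pairs, min_n = 4)
  row <- res[res$subgroup_var == "age_band" & res$subgroup == "13-18" &
    res$task_id == "shuttle_run", ]
  expect_equal(row$n_pairs, 3)
  expect_false(row$estimated)
  expect_true(is.na(row$icc))
})

test_that("interval bands separate stable and unstable retest windows", {
  mk <- function(icc, months, seed, prefix) {
    simulate_retest_pairs(sim_config(
      n = 200, seed = seed, id_prefix = prefix,
      retest = list(true_icc = flat_icc(icc), interval_months = months)
    ), tasks = "long_jump")
  }
  pairs <- dplyr::bind_rows(
    mk(0.85, c(1, 12), seed = 61, prefix = "S"),
    mk(0.30, c(13, 24), seed = 62, prefix = "L")
  )
  res <- subgroup_reliability(pairs,
    stratifiers = "interval", tasks = "long_jump"
  )
  short <- res[res$subgroup == "0-12", ]
  long <- res[res$subgroup == "12-24", ]
  expect_equal(short$classification, "stable")
  expect_equal(long$classification, "unstable")
})

test_that("the outcome partition keys on the 0.70 target", {
  icc <- c(
    backwards_tandem = 0.83, ins_and_outs = 0.73, long_jump = 0.81,
    jumping_jacks = 0.56, pylon_obstacle = 0.38, shuttle_run = 0.48
  )
  part <- select_outcome_items(icc)
  expect_setequal(
    part$outcome, c("backwards_tandem", "ins_and_outs", "long_jump")
  )
  expect_setequal(
    part$exertion, c("jumping_jacks", "pylon_obstacle", "shuttle_run")
  )
  # all reliable / none reliable edge cases
  expect_setequal(select_outcome_items(flat_icc(0.9))$outcome, cca_task_ids())
  expect_warning(
    none <- select_outcome_items(flat_icc(0.7)), # 0.70 itself does not pass
    "empty"
  )
  expect_length(none$outcome, 0)
  expect_error(
    select_outcome_items(icc[-1]),
    class = "ccakit_selection_error"
  )
})

test_that("the shipped published reliability table drives the partition", {
  pub <- cca_published_reliability()
  icc <- stats::setNames(
    pub$icc[pub$interval == "0-12"], pub$task_id[pub$interval == "0-12"]
  )
  part <- select_outcome_items(icc)
  expect_setequal(part$outcome, cca_outcome_items())
  expect_equal(
    classify_reliability(icc[["backwards_tandem"]]), "stable"
  )
})
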