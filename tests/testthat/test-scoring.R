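test_that("bin_score partitions the raw axis with the better-bin tie rule", {
  th <- c(8, 10, 12)
  # lower-better (timed): fastest bin is 4, a value on a cut point takes
  # the better adjacent bin
  expect_equal(bin_score(7.5, th, "lower_better"), 4L)
  expect_equal(bin_score(8, th, "lower_better"), 4L)
  expect_equal(bin_score(9, th, "lower_better"), 3L)
  expect_equal(bin_score(10, th, "lower_better"), 3L)
  expect_equal(bin_score(11.9, th, "lower_better"), 2L)
  expect_equal(bin_score(12, th, "lower_better"), 2L)
  expect_equal(bin_score(14.2, th, "lower_better"), 1L)
  # higher-better mirror: a 1.5 m jump at a 1.5 m top cut point scores 4
  expect_equal(bin_score(1.5, c(1.0, 1.25, 1.5), "higher_better"), 4L)
  expect_equal(bin_score(0.9, c(1.0, 1.25, 1.5), "higher_better"), 1L)
  expect_error(
    bin_score(5, c(3, 2, 1), "lower_better"),
    class = "ccakit_form_error"
  )
})

test_that("error rules reproduce the published anchors exactly", {
  rules <- cca_error_rules()
  # auto-zero thresholds
  expect_equal(apply_error_rule(4L, 1L, rules$jumping_jacks), 0L)
  expect_equal(apply_error_rule(4L, 1L, rules$pylon_obstacle), 0L)
  expect_equal(apply_error_rule(4L, 2L, rules$shuttle_run), 0L)
  expect_equal(apply_error_rule(4L, 3L, rules$ins_and_outs), 0L)
  expect_equal(apply_error_rule(4L, 5L, rules$backwards_tandem), 0L)
  # one-error caps
  expect_equal(apply_error_rule(4L, 1L, rules$backwards_tandem), 3L)
  expect_equal(apply_error_rule(4L, 1L, rules$ins_and_outs), 2L)
  expect_equal(apply_error_rule(4L, 1L, rules$shuttle_run), 1L)
  # zero errors leave the bin score unchanged
  for (rule in rules) {
    expect_equal(apply_error_rule(1:4, 0L, rule), 1:4)
  }
})

test_that("score_task agrees with the exhaustive lookup-table oracle", {
  form <- test_form()
  rules <- cca_error_rules()
  tasks <- cca_tasks()
  for (task in setdiff(cca_task_ids(), "long_jump")) {
    info <- tasks[tasks$task_id == task, ]
    reps <- bin_representatives(form$thresholds[[task]], info$direction)
    for (bin in 1:4) {
      for (errors in 0:6) {
        rec <- make_record(errors = stats::setNames(list(errors), task))
        rec[[paste0(task, "_raw")]] <- reps[5 - bin]
        got <- score_task(rec, task, form, rules[[task]])
        expect_identical(
          got, oracle_item_score(task, bin, errors),
          info = sprintf("%s bin=%d errors=%d", task, bin, errors)
        )
      }
    }
  }
})

test_that("item scores are monotone in performance and in errors", {
  form <- test_form()
  rules <- cca_error_rules()
  tasks <- cca_tasks()
  for (task in setdiff(cca_task_ids(), "long_jump")) {
    info <- tasks[tasks$task_id == task, ]
    reps <- bin_representatives(form$thresholds[[task]], info$direction)
    # reps ordered best -> worst; improving raw never lowers the score
    for (errors in 0:6) {
      scores <- vapply(reps, function(r) {
        rec <- make_record(errors = stats::setNames(list(errors), task))
        rec[[paste0(task, "_raw")]] <- r
        score_task(rec, task, form, rules[[task]])
      }, integer(1))
      expect_true(all(diff(scores) <= 0), info = task)
    }
    # with raw fixed, more errors never raise the score
    for (r in reps) {
      scores <- vapply(0:6, function(errors) {
        rec <- make_record(errors = stats::setNames(list(errors), task))
        rec[[paste0(task, "_raw")]] <- r
        score_task(rec, task, form, rules[[task]])
      }, integer(1))
      expect_true(all(diff(scores) <= 0), info = task)
      expect_true(all(scores >= 0 & scores <= 4))
    }
  }
})

test_that("standing long jump scores the best valid landing", {
  th <- c(1.0, 1.25, 1.5)
  # best valid distance is binned; 1.5 m at the top cut point scores 4
  expect_equal(score_long_jump(c(1.0, 1.6, 1.2), c(TRUE, TRUE, TRUE), th), 4L)
  # the 1.6 m jump does not count when its landing was invalid
  expect_equal(score_long_jump(c(1.0, 1.6, 1.2), c(TRUE, FALSE, TRUE), th), 2L)
  # no valid landing at all: unable to perform, score 0
  expect_equal(score_long_jump(c(1.0, 1.6, 1.2), rep(FALSE, 3), th), 0L)
  # single valid trial exactly at the lowest cut point takes the better bin
  expect_equal(score_long_jump(c(1.0, 2, 2), c(TRUE, FALSE, FALSE), th), 2L)
  expect_error(
    score_long_jump(c(1, 2), c(TRUE, TRUE), th),
    class = "ccakit_input_error"
  )
})

test_that("score_result sums the three outcome items into a 0-12 summary", {
  all4 <- stats::setNames(rep(4L, 6), cca_task_ids())
  expect_equal(score_result(all4)$outcome_summary, 12L)
  all0 <- stats::setNames(rep(0L, 6), cca_task_ids())
  expect_equal(score_result(all0)$outcome_summary, 0L)
  mixed <- all4
  mixed[c("backwards_tandem", "ins_and_outs", "long_jump")] <- c(3L, 2L, 4L)
  res <- score_result(mixed)
  expect_equal(res$outcome_summary, 9L)
  expect_equal(
    sort(names(res$exertion_scores)),
    sort(c("jumping_jacks", "pylon_obstacle", "shuttle_run"))
  )
  expect_error(
    score_result(all4[-1]),
    class = "ccakit_missing_data_error"
  )
})

test_that("score_sample applies the stratum-matched form", {
  # two strata with deliberately different ins-and-outs cut points
  base <- test_form()$thresholds
  shifted <- base
  shifted$ins_and_outs <- base$ins_and_outs + 2
  forms <- list(
    `female_9-12` = scoring_form(base,
      stratum = list(age_band = "9-12", sex = "female")
    ),
    `male_9-12` = scoring_form(shifted,
      stratum = list(age_band = "9-12", sex = "male")
    ),
    `female_13-18` = scoring_form(base,
      stratum = list(age_band = "13-18", sex = "female")
    ),
    `male_13-18` = scoring_form(base,
      stratum = list(age_band = "13-18", sex = "male")
    )
  )
  girl <- make_record(ins_and_outs_raw = 7.5)
  boy <- make_record(ins_and_outs_raw = 7.5, sex = "male")
  scored <- score_sample(dplyr::bind_rows(girl, boy), forms)
  # 7.5 s sits in bin 2 of the base form but beats every shifted cut point
  expect_equal(scored$score_ins_and_outs, c(2L, 4L))
  expect_equal(
    scored$outcome_summary,
    scored$score_backwards_tandem + scored$score_ins_and_outs +
      scored$score_long_jump
  )
})

test_that("missing raw values raise an addressed missing-data error", {
  rec <- make_record(shuttle_run_raw = NA_real_)
  expect_error(
    score_task(rec, "shuttle_run", test_form()),
    regexp = "shuttle_run",
    class = "ccakit_missing_data_error"
  )
})
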