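test_that("mean±SD cut points match hand-computed values", {
  # mean 12, SD 2: single lower-better cut at 12 - 2 = 10
  expect_equal(
    as.numeric(derive_mean_sd_thresholds(c(10, 12, 14), 1, "lower_better")),
    10,
    tolerance = 1e-12
  )
  expect_equal(
    as.numeric(derive_mean_sd_thresholds(c(10, 12, 14), 1, "higher_better")),
    14,
    tolerance = 1e-12
  )
  # second cut point twice as far from the mean
  two <- as.numeric(derive_mean_sd_thresholds(c(10, 12, 14), 2, "lower_better"))
  expect_equal(two, c(8, 10), tolerance = 1e-12)
  expect_equal(abs(two[1] - 12), 2 * abs(two[2] - 12), tolerance = 1e-12)
  expect_equal(
    as.numeric(derive_mean_sd_thresholds(c(10, 12, 14), 2, "higher_better")),
    c(14, 16),
    tolerance = 1e-12
  )
})

test_that("degenerate and undersized derivation inputs are flagged", {
  expect_warning(
    cuts <- derive_mean_sd_thresholds(c(5, 5, 5), 2, "lower_better"),
    "degenerate"
  )
  expect_equal(as.numeric(cuts), c(5, 5))
  expect_true(attr(cuts, "degenerate"))
  expect_error(
    derive_mean_sd_thresholds(3, 1, "lower_better"),
    class = "ccakit_derivation_error"
  )
  expect_warning(
    qcuts <- derive_quartile_thresholds(rep(2, 10), "lower_better"),
    "degenerate"
  )
  expect_true(attr(qcuts, "degenerate"))
  expect_error(
    derive_quartile_thresholds(1:3, "lower_better"),
    class = "ccakit_derivation_error"
  )
})

test_that("quartile cut points follow the linear-interpolation rule", {
  # frozen hand evaluation of type-7 quantiles on 1..8
  expect_equal(
    as.numeric(derive_quartile_thresholds(sample(1:8), "higher_better")),
    c(2.75, 4.50, 6.25),
    tolerance = 1e-12
  )
})

test_that("quartile-derived bins split a continuous sample into ~25% each", {
  set.seed(42)
  vals <- runif(10000, 5, 15)
  cuts <- derive_quartile_thresholds(vals, "lower_better")
  bins <- bin_score(vals, as.numeric(cuts), "lower_better")
  occ <- 100 * tabulate(bins, 4) / length(vals)
  expect_true(all(abs(occ - 25) < 1.5))
  # fastest quartile lands in bin 4
  expect_true(all(vals[bins == 4] <= as.numeric(cuts)[1]))
})

test_that("error-free filtering retains exactly the zero-error records", {
  s <- simulate_normative_sample(sim_config(n = 500, seed = 17))
  ef <- filter_error_free(s, "ins_and_outs")
  expect_equal(nrow(ef), sum(s$ins_and_outs_errors == 0))
  expect_true(all(ef$ins_and_outs_errors == 0))
  # long jump additionally requires a valid landing
  ef_lj <- filter_error_free(s, "long_jump")
  expect_true(all(
    ef_lj$long_jump_v1 | ef_lj$long_jump_v2 | ef_lj$long_jump_v3
  ))
  all_err <- s
  all_err$shuttle_run_errors <- 1L
  expect_error(
    filter_error_free(all_err, "shuttle_run"),
    class = "ccakit_derivation_error"
  )
})

test_that("Poisson error processes leave the expected error-free fraction", {
  tasks <- cca_task_params()
  tasks$shuttle_run$error_rate <- 0.25
  s <- simulate_normative_sample(sim_config(n = 10000, seed = 23, tasks = tasks))
  retained <- nrow(filter_error_free(s, "shuttle_run")) / nrow(s)
  expect_lt(abs(retained - exp(-0.25)), 0.02)
})

test_that("stratified derivation yields the four assessment forms", {
  s <- simulate_normative_sample(error_free_config(2000, seed = 29))
  forms <- build_scoring_forms(s, stratify = TRUE, seed = 29)
  expect_named(
    forms, c("female_9-12", "male_9-12", "female_13-18", "male_13-18"),
    ignore.order = TRUE
  )
  for (form in forms) {
    expect_s3_class(form, "cca_scoring_form")
    expect_length(form$thresholds, 6)
    expect_equal(form$provenance$seed, 29)
  }
  # provenance n sums to the stratum's error-free record count
  f <- forms[["female_9-12"]]
  n_stratum <- sum(s$sex == "female" & s$age <= 12)
  expect_equal(f$provenance$n_used$shuttle_run, n_stratum)
  # pooled derivation yields a single form; rebuilds are identical
  pooled <- build_scoring_forms(s, stratify = FALSE)
  expect_s3_class(pooled, "cca_scoring_form")
  expect_identical(pooled, build_scoring_forms(s, stratify = FALSE))
})

test_that("underfilled strata raise an error naming stratum and task", {
  s <- simulate_normative_sample(error_free_config(2000, seed = 29))
  s <- s[!(s$sex == "male" & s$age >= 13), ]
  expect_error(
    build_scoring_forms(s, stratify = TRUE),
    regexp = "male_13-18",
    class = "ccakit_derivation_error"
  )
})

test_that("records with errors cannot influence derived cut points", {
  s <- simulate_normative_sample(sim_config(n = 2000, seed = 37))
  form_before <- build_scoring_forms(s, stratify = FALSE)
  # corrupt the raw values of every error-committing record
  tampered <- s
  for (task in setdiff(cca_task_ids(), "long_jump")) {
    bad <- tampered[[paste0(task, "_errors")]] > 0
    tampered[[paste0(task, "_raw")]][bad] <- 1e6
  }
  bad_lj <- tampered$long_jump_errors > 0
  tampered$long_jump_d1[bad_lj] <- 1e6
  form_after <- build_scoring_forms(tampered, stratify = FALSE)
  expect_identical(form_before$thresholds, form_after$thresholds)
})

test_that("normative summaries are internally consistent", {
  s <- simulate_normative_sample(sim_config(n = 800, seed = 41))
  ns <- normative_summary(s, stratify = FALSE)
  expect_equal(nrow(ns), 6)
  expect_true(all(ns$n_error_free <= ns$n_total))
  expect_true(all(ns$q1 <= ns$q2 & ns$q2 <= ns$q3))
  expect_true(all(ns$sd >= 0))
})
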