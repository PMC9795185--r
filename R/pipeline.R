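#' Run the full instrument-development pipeline
#'
#' Executes the development stages end to end on a seeded synthetic cohort:
#' simulate a normative sample, derive scoring forms (pooled or stratified
#' by age band and sex), score every participant, compute item diagnostics,
#' simulate a paired retest cohort and estimate subgroup reliabilities, and
#' partition tasks into outcome and exertion items. Every artifact is
#' written under `out_dir` together with a manifest recording the
#' configuration, seed, package version, per-stage row counts and artifact
#' checksums; a rerun with the same configuration reproduces every artifact
#' byte for byte.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed driving all randomness.
#' @param n Normative sample size.
#' @param n_retest Retest cohort size.
#' @param method Cut-point method, `"quartile_5pt"` or `"mean_sd_4pt"`.
#' @param stratify Derive four age-band x sex forms instead of one pooled
#'   form.
#' @param config Optional pre-built [sim_config()] overriding `n`/`seed`
#'   for the normative stage.
#' @param min_n Minimum error-free records per task and stratum.
#' @return Invisibly, a list with the in-memory artifacts (`sample`,
#'   `forms`, `scores`, `diagnostics`, `reliability`, `items`, `manifest`).
#' @examples
#' \donttest{
#' res <- run_pipeline(tempfile("cca"), seed = 1, n = 400, n_retest = 120)
#' res$items
#' }
#' @export
run_pipeline <- function(out_dir, seed = 20221214L, n = 854, n_retest = 67,
                         method = c("quartile_5pt", "mean_sd_4pt"),
                         stratify = TRUE, config = NULL, min_n = 30) {
  method <- match.arg(method)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- "simulate"
  counts <- list()
  on.exit({
    if (!is.null(stage)) {
      file.create(file.path(out_dir, paste0(stage, ".failed")))
    }
  })
  log_stage <- function(name, rows_in, rows_out) {
    message(sprintf(
      "[ccakit] %-11s in=%d out=%d", name, rows_in, rows_out
    ))
    counts[[name]] <<- list(rows_in = rows_in, rows_out = rows_out)
  }

  if (is.null(config)) config <- sim_config(n = n, seed = as.integer(seed))
  sample <- simulate_normative_sample(config)
  write_athlete_csv(sample, file.path(out_dir, "normative_sample.csv"))
  log_stage("simulate", config$n, nrow(sample))

  stage <- "derive"
  forms <- build_scoring_forms(
    sample,
    method = method, stratify = stratify, min_n = min_n,
    sample_id = "synthetic-normative", seed = config$seed
  )
  write_scoring_forms(forms, file.path(out_dir, "scoring_forms.json"))
  summary_tbl <- normative_summary(sample, stratify = stratify)
  readr::write_csv(summary_tbl, file.path(out_dir, "normative_summary.csv"))
  n_forms <- if (inherits(forms, "cca_scoring_form")) 1L else length(forms)
  log_stage("derive", nrow(sample), n_forms)

  stage <- "score"
  scores <- score_sample(sample, forms)
  readr::write_csv(scores, file.path(out_dir, "scores.csv"))
  log_stage("score", nrow(sample), nrow(scores))

  stage <- "diagnose"
  diagnostics <- diagnose_items(scores, sample = sample, scale_max = 4)
  readr::write_csv(diagnostics, file.path(out_dir, "diagnostics.csv"))
  log_stage("diagnose", nrow(scores), nrow(diagnostics))

  stage <- "reliability"
  retest_config <- sim_config(
    n = n_retest, seed = (as.integer(seed) + 1L) %% 2147483629L,
    tasks = config$tasks, retest = config$retest,
    id_prefix = "R"
  )
  pairs <- simulate_retest_pairs(retest_config)
  write_retest_csv(pairs, file.path(out_dir, "retest_pairs.csv"))
  reliability <- subgroup_reliability(pairs)
  readr::write_csv(reliability, file.path(out_dir, "reliability.csv"))
  items <- tryCatch(
    select_outcome_items(reliability, interval = "0-12"),
    ccakit_selection_error = function(e) NULL
  )
  log_stage("reliability", nrow(pairs), nrow(reliability))

  stage <- "manifest"
  artifacts <- c(
    "normative_sample.csv", "scoring_forms.json", "normative_summary.csv",
    "scores.csv", "diagnostics.csv", "retest_pairs.csv", "reliability.csv"
  )
  manifest <- list(
    package = "ccakit",
    package_version = as.character(utils::packageVersion("ccakit")),
    seed = as.integer(seed),
    config = list(
      n = config$n, n_retest = n_retest, method = method,
      stratify = stratify, min_n = min_n
    ),
    items = items,
    stages = counts,
    checksums = as.list(tools::md5sum(file.path(out_dir, artifacts)))
  )
  names(manifest$checksums) <- artifacts
  jsonlite::write_json(
    manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  stage <- NULL
  invisible(list(
    sample = sample, forms = forms, scores = scores,
    diagnostics = diagnostics, reliability = reliability,
    items = items, manifest = manifest
  ))
}
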