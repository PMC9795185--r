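# ccakit

Development and evaluation toolkit for the **Concussion Challenge
Assessment (CCA)**, a six-task gross motor assessment for paediatric
concussion. The package is aimed at clinimetricians and rehabilitation
researchers building or auditing performance-based outcome measures: it
implements the full development pipeline — normative cut-point derivation,
error-modified ordinal scoring, item-difficulty/ceiling diagnostics, and
test–retest reliability — on reproducible synthetic cohorts, since no
participant-level normative data are distributed with the instrument.

## The model in brief

Each task yields a raw measure (time in seconds, repetitions, or jump
distance in metres) plus an error count. An item score in 0–4 is produced
in two steps:

1. **Binning** — three cut points, the quartiles *(Q1, Q2, Q3)* of an
   error-free normative sample, partition the raw axis into four bins;
   the best quartile scores 4, the worst 1. A value exactly on a cut point
   takes the better bin (a 1.5 m long jump at a 1.5 m top cut point
   scores 4). A legacy mean ± SD method (cuts at μ ± σ and μ ± 2σ) is also
   provided.
2. **Error modification** — the error count *e* caps or zeroes the bin
   score: score 0 at *e* ≥ 1 (Jumping Jacks, Pylon Obstacle Course),
   *e* ≥ 2 (Modified Shuttle Run), *e* ≥ 3 (Ins and Outs) or *e* ≥ 5
   (Backwards Tandem Walking); below those counts the maximum attainable
   score with one error is 3 (Backwards Tandem), 2 (Ins and Outs) or
   1 (Shuttle Run). The Standing Long Jump scores the best of three trials
   and is 0 only when no trial has a valid two-foot landing.

The follow-up summary is the sum of the three **outcome items**
(Backwards Tandem Walking + Ins and Outs + Standing Long Jump, 0–12);
the other three tasks are standalone **exertion items**. The partition is
driven by single-measure test–retest reliability, estimated as the two-way
random-effects absolute-agreement ICC,

    ICC(A,1) = (MS_R − MS_E) / (MS_R + (k−1)·MS_E + (k/n)·(MS_C − MS_E)),

with F-based 95% confidence intervals and the three-band rule
(unstable < 0.60 ≤ marginal ≤ 0.70 < stable): tasks with whole-group
ICC > 0.70 at a 0–12-month retest interval qualify as outcome items.

## Worked example

Derive a pooled quartile scoring form from a seeded synthetic normative
cohort of 854 athletes, then score one athlete:

```r
library(ccakit)

cfg    <- sim_config(n = 854, seed = 20221214)
sample <- simulate_normative_sample(cfg)
form   <- build_scoring_forms(sample, stratify = FALSE)
form
#> <cca_scoring_form> quartile_5pt
#>   stratum: pooled
#>   jumping_jacks      22, 24, 25
#>   pylon_obstacle     6.2145, 6.7285, 7.3162
#>   backwards_tandem   15.145, 18.425, 23.12
#>   shuttle_run        17.673, 18.719, 19.758
#>   ins_and_outs       5.6604, 6.5192, 7.6769
#>   long_jump          1.505, 1.6644, 1.8436
```

Cut points are in raw units (seconds / repetitions / metres): a shuttle
run faster than 17.67 s sits in the top bin, a long jump past 1.84 m
likewise. Scoring an athlete who walked the backwards tandem line in
16.2 s (top-bin speed) **with one error**, and jumped 1.52 m at best:

```r
athlete <- tibble::tibble(
  participant_id = "A104", age = 11L, sex = "female", session = "t1",
  jumping_jacks_raw = 24, jumping_jacks_errors = 0L,
  pylon_obstacle_raw = 6.9, pylon_obstacle_errors = 0L,
  backwards_tandem_raw = 16.2, backwards_tandem_errors = 1L,
  shuttle_run_raw = 18.1, shuttle_run_errors = 0L,
  ins_and_outs_raw = 5.4, ins_and_outs_errors = 0L,
  long_jump_d1 = 1.31, long_jump_d2 = 1.52, long_jump_d3 = 1.44,
  long_jump_v1 = TRUE, long_jump_v2 = TRUE, long_jump_v3 = TRUE,
  long_jump_errors = 0L
)
score_sample(athlete, form)
#>   participant_id session age    sex score_jumping_jacks score_pylon_obstacle
#> 1           A104      t1  11 female                   3                    2
#>   score_backwards_tandem score_shuttle_run score_ins_and_outs score_long_jump
#> 1                      3                 3                  4               2
#>   outcome_summary
#> 1               9
```

The one tandem-walk error capped a top-bin performance at 3; the summary
score 9/12 is the sum of the three outcome items (3 + 4 + 2).

Reliability on a paired synthetic retest cohort, and the item partition:

```r
pairs <- simulate_retest_pairs(sim_config(n = 300, seed = 20221215))
rel   <- subgroup_reliability(pairs)
subset(rel, subgroup_var == "interval" & subgroup == "0-12")
#>            task_id n_pairs   icc ci_lower ci_upper classification
#> 1    jumping_jacks     140 0.682    0.583    0.762       marginal
#> 2   pylon_obstacle     140 0.403    0.255    0.533       unstable
#> 3 backwards_tandem     140 0.840    0.784    0.883         stable
#> 4      shuttle_run     140 0.359    0.207    0.495       unstable
#> 5     ins_and_outs     140 0.704    0.610    0.779         stable
#> 6        long_jump     140 0.829    0.769    0.875         stable

select_outcome_items(rel)
#> $outcome
#> [1] "backwards_tandem" "ins_and_outs"     "long_jump"
#> $exertion
#> [1] "jumping_jacks"  "pylon_obstacle" "shuttle_run"
```

The generator's default per-task reliabilities are the published
whole-group estimates, so the simulated cohort recovers the instrument's
outcome/exertion partition. `run_pipeline()` executes all stages end to
end and writes CSV/JSON artifacts with a checksummed manifest;
`inst/cli/cca.R` exposes the same stages as shell subcommands
(`simulate`, `derive`, `score`, `diagnose`, `reliability`, `pipeline`).

See the vignette (`vignettes/cca-development.Rmd`) for the full methods
account: distributional assumptions of the generator, derivation and
tie-break conventions, ICC formulas and CI construction, and limitations.

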