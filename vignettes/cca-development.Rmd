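---
title: "Developing and evaluating the Concussion Challenge Assessment scoring system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Developing and evaluating the Concussion Challenge Assessment scoring system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(ccakit)
```

## The instrument and its measurement model

The Concussion Challenge Assessment (CCA) is a six-task gross motor
assessment for youth recovering from concussion. Each task yields a raw
performance measure — time to complete (Pylon Obstacle Course, Backwards
Tandem Walking, Modified Shuttle Run, Ins and Outs), repetitions (Jumping
Jacks), or jump distance (Standing Long Jump, best of three trials) — plus
a count of performance errors (a touched pylon, a non-tandem step, a missed
start line). Scoring converts the raw measure into an ordinal 0–4 item
score in two steps:

1. **Binning.** Three cut points partition the raw axis into four
   performance bins; the best quartile of an error-free normative sample
   maps to bin 4 and the worst to bin 1 (`bin_score()`).
2. **Error modification.** The recorded error count caps or zeroes the bin
   score (`apply_error_rule()`). Tasks where errors are rare in healthy
   athletes zero the score at one error (Jumping Jacks, Pylon Obstacle
   Course) or two (Modified Shuttle Run); tasks where errors are common
   allow graded caps — with one error the maximum attainable score is 3 for
   Backwards Tandem Walking, 2 for Ins and Outs, and 1 for the Shuttle Run.
   Backwards Tandem Walking scores 0 only at five or more errors.

Score 0 is reserved for error-driven failure (or, for the long jump,
inability to land any of the three trials on two feet); an error-free but
slow performance bottoms out at 1. The follow-up summary score is the
unweighted sum of the three *outcome* items — Backwards Tandem Walking, Ins
and Outs, Standing Long Jump — on a 0–12 scale, while the three *exertion*
items are standalone single-time-point scores.

```{r}
rules <- cca_error_rules()
rules$backwards_tandem
```

Two documented conventions resolve ambiguities in the published scoring
narrative. First, a raw value exactly on a cut point takes the *better*
adjacent bin; this is anchored by the worked example that a 1.5 m standing
long jump scores 4 under a form whose top cut point is 1.5 m. Second, the
graded caps not individually printed are filled in monotonically from the
printed anchors: Backwards Tandem Walking's cap falls one score point per
additional error (floored at 1), and Ins and Outs caps at 1 with two
errors. An exhaustive lookup-table oracle in the test suite pins the full
bin-by-error score surface for all six tasks.

## Deriving cut points from a normative sample

Cut points are derived from **error-free performances only** — a
participant sacrificing accuracy for speed must not drag the cut points —
and, for the long jump, from the best valid-landing distance
(`filter_error_free()`). Two derivation methods are provided:

* **Mean ± SD (legacy 4-point forms).** The single cut point sits 1 SD from
  the mean on the better side (e.g. at mean − 1 SD for timed tasks, so the
  top category requires performing at least 1 SD better than average); a
  second cut point, when used, sits at 2 SD.
* **Quartiles (final 5-point forms).** The three cut points are the 25th,
  50th and 75th percentiles of the error-free distribution, computed with
  linear interpolation between order statistics (the type-7 quantile
  convention) so derivations are bit-reproducible. Applied back to its
  derivation sample, a quartile form occupies each bin with ≈25% of
  records. For discrete measures (jumping-jack repetitions) the mass tied
  exactly at an integer cut point is assigned the better bin, so occupancy
  deviates from 25% by exactly that tie mass; this is a property of
  discreteness, not of the derivation.

`build_scoring_forms()` derives either one pooled form or four stratified
forms — female/male children (9–12 years) and female/male adolescents
(13–18 years) — since performance improves with age and differs by sex on
strength and speed tasks. The 13–18 band is used throughout. Each
stratum-task derivation requires a minimum error-free count (default 30,
configurable); an underfilled stratum fails loudly naming the stratum and
task rather than producing fragile cut points. Zero-spread derivation
values yield a degenerate (tied) form, flagged and warned about but
representable.

```{r}
sample <- simulate_normative_sample(sim_config(n = 2000, seed = 1))
forms <- build_scoring_forms(sample, stratify = TRUE, seed = 1)
forms[["female_9-12"]]
```

## Item diagnostics

`item_diagnostics()` evaluates a scored sample per item: mean and SD of the
item scores, adjusted Fisher–Pearson skewness, and the percentage at the
scale maximum. On the legacy 0–3 scale a mean below 2.0 flags
`too_difficult` (the historical acceptability criterion; its "SD of 1.0"
companion is reported but not enforced as a flag). A ceiling effect — many
healthy athletes at a perfect score, masking post-injury decline — is
flagged when the share at the maximum exceeds 15% or skewness falls below
−0.5; both bounds are configurable and deliberately conservative, since the
published account describes the effect qualitatively. On the 0–4 scale only
the ceiling/skew flags apply. `error_prevalence()` reports the share of
participants committing at least one error and recommends the error-rule
class (auto-zero below 5% prevalence, graded caps otherwise).

## Test–retest reliability

Reliability is estimated on the **raw measures** (seconds, repetitions,
metres) from paired sessions, using the single-measure intraclass
correlation. The two-way random-effects, absolute-agreement form ICC(A,1)
is the default because assessors differed between sessions, so systematic
session/assessor shifts must count against agreement:

$$\mathrm{ICC}(A,1) = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E)}$$

with subject, session and residual mean squares computed directly from the
paired data and $k = 2$. Confidence intervals use the F-based approximation
with Satterthwaite degrees of freedom; negative estimates are reported as
computed, not truncated. A one-way random-effects form is available via
`model = "one_way"`. Stability classification follows the three-band rule —
unstable below 0.60, marginal from 0.60 to 0.70 (inclusive at both
boundaries), stable above 0.70.

`subgroup_reliability()` reports each task for the whole group and within
retest-interval band (0–12 vs 12–24 months, with "up to 12" inclusive), age
band and sex, with group means/SDs at both sessions. Subgroups below the
minimum pair count (default 4) are flagged rather than estimated.
`select_outcome_items()` applies the partition rule: tasks whose
whole-group ICC exceeds 0.70 in the 0–12-month band join the outcome set;
the remainder are retained as exertion items. Applied to the published
whole-group estimates shipped with the package, this reproduces the
instrument's final composition:

```{r}
pub <- cca_published_reliability()
short <- subset(pub, interval == "0-12")
select_outcome_items(setNames(short$icc, short$task_id))
```

## What the synthetic cohorts emulate — and what they do not

No participant-level data are distributed with the instrument, so the
package ships a seeded generator whose defaults encode the normative study
conditions: 854 athletes aged 9–18, balanced sexes, and a 67-athlete
retest cohort with intervals from 2 weeks to 24 months.

* **Performance distributions.** Timed tasks are lognormal (positive
  support, the right skew typical of timed motor tasks); repetitions are a
  rounded normal truncated at zero; jump distances are truncated normal
  with a shared within-participant ability component across the three
  trials. Pooled locations/scales default to published session-1 summaries
  where available (e.g. ≈23 jumping jacks, ≈6.8 s pylon course, ≈19 s
  backwards tandem walk); the long jump defaults to 1.55 m ± 0.25 m, a
  realistic youth-athlete range consistent with the 1.5 m top-score worked
  example. Age (adolescent vs child) and sex shift locations additively in
  the direction of better performance with age/male sex on speed and
  strength tasks.
* **Error processes.** Error counts are Poisson with task-specific rates
  solved from published error prevalences (1.8% of participants for jumping
  jacks up to 55.3% for the backwards tandem walk) via
  $P(N \ge 1) = 1 - e^{-\lambda}$. Long-jump landing validity is Bernoulli
  per trial with a 3.6% default failure rate.
* **Retest pairs.** Sessions are subject effect plus occasion noise on the
  natural scale. The realized demographic (stratum-shift) variance counts
  toward the between-subject share, and the random subject effect is sized
  so that between-subject variance is exactly the target fraction
  `true_icc` of the total; the cohort's population ICC therefore equals
  `true_icc`, and the generator warns if demographic heterogeneity alone
  exceeds the requested share. Default per-task `true_icc` values are the
  published 0–12-month whole-group estimates.

The generator does **not** model anthropometrics, practice/learning effects
between sessions, assessor identity, correlations between tasks within a
participant (beyond shared demographics), or the error taxonomy of the
licensed administration manual. Consequently, passing tests demonstrate
that the derivation, scoring, diagnostic and reliability machinery is
correct under the stated statistical structure — not that real athlete data
follow that structure, and not that the licensed normative cut points are
reproduced (they are not reproducible without the raw data and are out of
scope).

## Numerical choices and problem sizes

* All randomness flows from the single config seed; per-task sub-streams
  are derived deterministically, and the caller's RNG state is restored, so
  identical configurations are byte-reproducible end to end (the pipeline
  manifest records artifact checksums to make this checkable).
* Quantiles are type 7; scoring-form JSON is written with 17 significant
  digits so a write/read round trip reproduces cut points bit-exactly.
* ICC estimation requires at least 4 complete pairs; degenerate
  perfect-agreement data return ICC 1 with a collapsed interval; constant
  data (no variance anywhere) are an error rather than a number.
* Test and pipeline problem sizes were chosen to bound Monte-Carlo error
  well below the assertion tolerances at interactive runtimes: quartile
  occupancy on 10,000-record samples, ICC oracle agreement on 100 small
  samples (n 4–50, tolerance 1e-10), reliability recovery at n = 500
  (±0.05), generator calibration as the mean of three n = 5000 cohorts
  (±0.02), and 95% CI coverage over 1000 replicates at n = 50 (93–97%).

## Limitations

The package implements the *development machinery* of the instrument. It
does not ship the licensed administration/scoring manual, does not detect
errors from sensor data, and makes no claims about concussed populations:
clinical validation, responsiveness to change, and rater-reliability in
injured youth remain external questions. The published long-jump group
summaries are inconsistent with metres for this age range (likely a unit
artifact in the source table); reliability here treats units as
pass-through, and the discrepancy is documented rather than resolved.
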