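---
title: "Computer-tailored step advice: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computer-tailored step advice: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(steptailor)
```

`steptailor` automates the individual counselling loop of a
pedometer-based physical-activity intervention: measure a person's daily
step level, place them on the behaviour-change continuum, and assemble
feedback matched to where they stand relative to the 10,000 steps/day
goal. This vignette documents the procedures, the parameters that matter,
and the reasoning behind every choice the underlying literature leaves
open.

## Step-log processing

A participant wears a pedometer for 7 consecutive days and records, per
day, the step count and any non-ambulatory activities with their
duration. Processing runs in a fixed order per day:

1. **Activity conversion.** Biking and swimming do not register on a
   waist-worn pedometer, so each reported minute of them is credited at
   `conversion_rate = 150` steps/minute. The convertible set is
   configurable; only these two kinds are in it by default.
2. **Truncation.** The adjusted daily total is capped at
   `cap = 20000` steps/day to limit unrealistically high values.
   Adjustment runs *before* truncation on purpose: the cap bounds the
   day's total exposure, including converted activity. The protocol
   literature states the cap only for the analysis stage; we apply it
   uniformly in the advice path too, since a tailoring engine acting on
   an implausible 40,000-step day would otherwise produce a different
   stage than the analysis sees.
3. **Averaging.** The summary is the arithmetic mean over *valid* days
   (days with a recorded count; a recorded 0 is valid, a missing value is
   not). At least `min_valid_days = 5` valid days are required; shorter
   logs raise a typed `insufficient-data` error rather than a silent
   low-precision mean. The 7-day protocol length is advisory, not
   enforced, so 6-day logs still summarise.

The mean is kept as a real number throughout; rounding happens only when
messages are rendered.

## Stage classification and address mode

The transtheoretical model names the stages but no operational cutoffs
for a step-count context, so the package adopts the standard
definitions, keyed on goal status, intention, and how long the goal has
been held:

| condition | stage | address mode |
|---|---|---|
| below goal, no intention | precontemplation | impersonal ("people could…") |
| below goal, intention within 6 months | contemplation | personal ("you could…") |
| below goal, intention within 1 month | preparation | decisive ("you should…") |
| at/above goal, < 6 months | action | supportive ("you do…") |
| at/above goal, ≥ 6 months | maintenance | supportive |

The goal comparison is inclusive (exactly 10,000 steps/day counts as at
goal), and the action/maintenance boundary is the conventional 6 months
(`maintenance_months`, configurable). Intention is required only below
goal; at goal it may be missing, since the rule table never consults it
there. The classifier is total and deterministic over the whole
cross-product, which the test suite checks exhaustively.

## Advice composition

A document always carries its sections in a fixed order: introduction,
normative feedback, progress feedback, schedule, tips, information
blocks. Section presence is rule-driven:

- **Introduction** — the stage's canonical text, shipped verbatim in the
  message library and golden-tested.
- **Normative feedback** — the measured mean against the goal, with the
  gap (`goal − mean`, floored at 0) filled into the below-goal or
  at-goal variant.
- **Progress feedback** — only from the second advice request onward. The
  current level is compared with the level at the previous request;
  changes beyond `stable_band = 500` steps/day in either direction are
  *positive* or *negative evolution*, anything inside the band is
  *stable*. The source literature names only the positive/negative
  categories; the band (half the smallest weekly increment) exists so
  that week-to-week measurement noise is not fed back as progress or
  relapse, and the three categories partition all pairs of levels.
- **Schedule** — below-goal stages only. Weekly targets
  `baseline + k·increment` for the participant's chosen increment
  (500 or 1000 steps/week), with the final week capped at the goal, so
  `weeks_to_goal = ⌈(goal − baseline)/increment⌉`.
- **Tips** — grouped by life domain (work, household chores, gardening,
  leisure, transport). Below-goal stages receive step-increase tips in
  the stage's address mode; action and maintenance receive
  relapse-prevention framing and no push to step more. A barrier-coping
  group appears for below-goal participants whose perceived-barriers
  score is high.
- **Information blocks** — walking buddy, step vs activity guidelines,
  pedometer use, benefits of 10,000 steps/day, plus conditional blocks on
  barriers and self-efficacy, and the local environment.

Psychosocial scores are treated as 1–5 ordinals (the original
instrument's anchors are unpublished); "high barriers" defaults to ≥ 4
and "low self-efficacy" to ≤ 2 (`barrier_threshold`,
`self_efficacy_threshold`). The message library is an external YAML file
so wording can change without code changes; only the five stage
introductions are canonical, all other texts are this package's own
seed wording. Every emitted message records its library id and the
predicate that admitted it, making each document auditable, and
rendering (text, Markdown, HTML) is deterministic: the same document is
byte-identical on re-render.

## Evaluation statistics

- **Welch t from summaries.** Baseline tables report only (n, mean, SD),
  so the two-sample t is computed from summaries:
  `t = (m₁−m₂)/√(s₁²/n₁+s₂²/n₂)` with Satterthwaite df. Welch is the
  default because the degrees of freedom printed in the trial tables
  this layer reproduces (e.g. t₁₅ for groups of 30 and 13) match
  Satterthwaite, not pooled, df; a pooled variant sits behind
  `pooled = TRUE`. When both variances vanish the statistic is 0 and the
  df fall back to `n₁+n₂−2` (the formula's limit).
- **Pearson χ²** on r×c counts with margin-based expected values, *no*
  Yates continuity correction (the printed 2×2 values match the
  uncorrected statistic). Zero margins are an error, not an NaN.
- **Log transform.** Right-skewed minutes/day outcomes (walking, total
  physical activity) are tested on `log(x + 1)`; the offset handles the
  many genuine zeros and maps 0 to 0. All displayed means and SDs stay
  on the raw scale.
- **Mixed repeated-measures ANOVA.** With two timepoints the
  within-subject stratum of the split-plot design reduces to the change
  scores `d = post − base`:
  `SS_time = N·d̄²/2`, `SS_int = Σ n_g (d̄_g − d̄)²/2`,
  `SS_err = Σ (dᵢ − d̄_g)²/2`, each F on (1, N−2) df. This sequential
  decomposition coincides with `aov(y ~ cond*time + Error(id))`, which
  the tests use as an independent cross-check alongside a hand-written
  projection oracle. Per-arm change CIs use the t distribution on the
  within-arm change scores (the construction is not described in the
  source literature; this is the standard one-sample interval). Only
  participants with both timepoints enter; the intent-to-treat path
  first carries baseline forward for every missing postintervention
  value (making dropouts' change exactly 0), an operation that is
  idempotent by construction.
- No multiplicity adjustment is applied, matching the evaluation design
  this layer reproduces; significance is nominal at .05.

## The synthetic cohort generator

`cohort_spec()` defaults describe the study conditions this pipeline is
meant for: two arms of 46, baseline marginals per arm and outcome
matching a mostly inactive primary-care sample (steps ≈ 8600–8900, SD ≈
3370; BMI ≈ 26; walking ≈ 33–45 min/day; sitting ≈ 7 h/day), a dropout
probability of 23/92 = 0.25, a shared secular step increase of 2639
steps/day, and no differential condition effect.

Baselines are truncated-normal (at 0, and at the 20,000 cap for steps).
Postintervention values follow
`mu + ρ·(base − mu) + secular + effect + e` with
`e ~ N(0, sd·√(1−ρ²))`, so the postintervention SD equals the baseline
SD and the baseline–post correlation is `ρ = 0.7` — both free parameters
in reality (only means and SDs are published), fixed here at values
typical for repeated step measurements and configurable. Postintervention
values are then *clipped* to the outcome bounds rather than re-drawn;
with the default marginals fewer than 1% of draws touch a bound, but the
clipping does shave a few percent off a large injected mean change near
the cap (visible as a realized secular change slightly under the
injected 2639).

What the generator does **not** emulate: the skewness and zero-inflation
of real self-reported minutes (it truncates a normal instead), weekday
vs weekend structure in step counts, seasonality, and informative
dropout (dropout is Bernoulli, independent of outcomes). Tests passing
on these cohorts therefore demonstrate correctness of the computations
and calibration of the tests under near-ideal distributional conditions,
not robustness to real-world messiness.

Two simulation helpers quantify calibration: the rejection rate of the
interaction test under a zero effect (nominal size), and the recovery of
an injected step effect as the between-arm difference in mean change.
The test suite runs 1000 replicates at 46 per arm for the size check and
smaller replicate counts (60–150) for recovery; the acceptance script
uses 1000 and 150. These sizes keep the full suite under half a minute
while leaving the binomial error of the size estimate (≈ 0.7 points)
well inside the ±1.5-point acceptance band.

## Degenerate inputs and numerical conventions

- Zero-variance ANOVA error with a nonzero effect SS reports `F = Inf`;
  with a zero effect SS it reports `F = 0` (0/0 treated as no effect).
- Ties: a change exactly on the `stable_band` boundary is stable; a mean
  exactly on the goal is at goal; a maintenance duration exactly 6
  months is maintenance.
- Schedules from a baseline already at goal are empty (0 weeks), not an
  error.
- All randomness flows through explicit seeds (`rng_seed` in specs,
  `seed` in simulation helpers); a `NULL` seed continues the caller's
  RNG stream so replicate loops don't collapse onto one draw.

## Known limitations

- Only the five stage introductions are canonical wording; all other
  message texts are this package's own and should be reviewed by a
  health-communication specialist before field use.
- The questionnaire covers the fields the tailoring rules consume, not
  the full diagnostic instrument (IPAQ outcomes enter already scored as
  minutes/day and hours/day).
- The ANOVA layer is the classical two-timepoint split-plot; it does not
  generalise to more timepoints, covariates, or mixed-effects models,
  and the comparison tables assume exactly two groups.
- Web delivery, reminder scheduling, and localisation are out of scope;
  `request_number` is an input, not a scheduler.
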