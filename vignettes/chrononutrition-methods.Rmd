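---
title: "Chrononutrition metrics for rotating-shift schedules: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chrononutrition metrics for rotating-shift schedules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chrononutr)
```

## The problem

Rotating-shift workers (the motivating cohort is police officers alternating
9--12 h morning, evening and night shifts with rest days) eat at times
dictated by their schedule. Characterizing *when* calories are consumed --
relative to the clock, to waking, and to work -- requires more care than a
standard dietary analysis, because the analysis day is not midnight-to-
midnight and because meal timing lives on a circle. `chrononutr` implements
that analysis end to end and ships a synthetic-data generator so that every
stage can be validated without access to individual-level data.

## The analysis day

A **day window** runs from the wake time of the main sleep episode preceding
a shift or rest day to the wake time of the following main sleep. The **main
sleep** is the longest sleep episode of a calendar day; all others are naps.
Day types are assigned from the work period a window encloses:

* *morning*: work starts between 0500 h and 0900 h;
* *evening*: work ends between 2200 h and 0200 h;
* *night*: the work interval contains the whole 0100--0500 h span;
* *rest*: no work period in the window.

Precedence is night > evening > morning, which makes the overlapping rules
deterministic; every shift of the cohort's catalogue satisfies exactly the
intended rule. "Contains the whole 0100--0500 h span" is a deliberate
reading of the night rule: all catalogued night shifts satisfy it, and it
prevents double-labelling. A consequence is that a hypothetical 1800--0300
shift is *unclassified* (it ends after 0200 and covers only part of the
night core); unclassified and duration-excluded shifts (shorter than 4.5 h
or longer than 13.5 h) drop their day from day-type analyses.

**Sleep-to-day attribution.** Episodes are grouped by the calendar date of
their *wake* time (configurable to onset date). With the cohort's own sleep
timing -- post-evening-shift sleep beginning around 0111 h and the following
rest-day sleep around 2256 h -- onset-date grouping puts two long sleeps on
one calendar day, demotes one to a nap, and destroys every evening-to-rest
transition window (spans of ~47 h). Wake-date grouping yields exactly one
main sleep per day across the entire roster. Ties in duration go to the
earlier onset.

Day windows are kept only when their length is inside (12, 36) h; everything
else is logged with a reason, never silently dropped.

## Intake events

Meal logs arrive as timestamped records with kcal and macronutrient kcal
(carbohydrate, sugar, fat, saturated fat, protein, alcohol). Records of the
same meal type within 15 min merge into one **intake event** carrying the
last member's timestamp and summed calories. Merging is *chained*
(A--B <= 15 min and B--C <= 15 min merge all three) and operates within each
(subject, meal type) series, so an interleaved record of a different type
does not break a chain; this matches the "timestamp of the last meal"
semantics and is verified in the tests against a brute-force
transitive-closure oracle. Merging conserves every kcal field exactly and is
idempotent.

Within a window, an event's **time awake** is the elapsed time since window
start minus intervening sleep; an event falling inside a nap is credited
only for the portion of the nap not yet slept. Timing metrics (first-meal
latency, last meal to sleep onset, eating window, circular statistics) use
only events strictly above 5 kcal -- the threshold is strict, so a 5 kcal
event is excluded -- and require at least `min_events = 2` qualifying events
(days with fewer are excluded from timing analyses but retained for caloric
totals). Totals always use all events.

## Metrics

* **%BMR**: intake is standardized to the Mifflin--St Jeor basal metabolic
  rate (10 w + 6.25 h - 5 a + 5 for males, -161 for females; the original
  unrounded coefficients are available via an argument) and weighted by day
  length: `100 * kcal / (BMR * day_length / 24)`. Macro %BMR components sum
  to the total by construction.
* **Circular summary**: event clock times map to angles
  (theta = 2 pi h / 24); the kcal-weighted resultant gives the mean intake
  time, its length rho in [0, 1] measures concentration, and the circular
  SD is `sqrt(-2 log rho) * 24 / (2 pi)` hours. When rho is numerically
  zero the mean is reported as undefined (`NA`).
* **Night and work fractions**: percent of kcal with clock time in
  [2300, 0600) -- half-open on both analyses' boundaries, a convention the
  source analysis leaves unstated -- and percent with timestamps inside the
  closed work interval (at-work is `NA` on rest days; days with intake but
  none at night/work score an explicit 0).
* **Binned distributions**: percent of daily kcal per half-open 4-h bin by
  clock time (six bins) and by time awake; bins are zero-filled and sum to
  100 whenever there is intake.

A day-window may contain the 2300--0600 span twice (long night-shift
windows); all events whose clock time falls in the span are counted, as the
metric is defined on clock time.

## Statistics

Day-type comparisons use linear mixed-effects models
(`outcome ~ day_type + sex + age + (1 | subject)`, REML via `lme4`) with a
Wald F for the day-type omnibus effect and all pairwise day-type contrasts,
Benjamini--Hochberg adjusted within their family. Families follow the report
tables: intake/%BMR outcomes, timing outcomes, at-night, at-work, and
overall macronutrient shares are adjusted separately. Denominator degrees of
freedom use a between-within (containment) approximation
`n_obs - n_subjects - q`; a Satterthwaite approximation would require
machinery out of proportion for this package, and at the cohort's scale
(90 observations, 31 subjects) the two differ by a few df at most. Singular
fits fall back to a fixed-effects model with a warning.

Group-level comparisons of mean intake *times* use the Watson--Williams
high-concentration F test on one angle per subject-day (each subject-day's
kcal-weighted mean time enters unweighted; whether the original analysis
weighted these is unstated). The concentration parameter is estimated from
the pooled mean resultant length via the standard three-piece inverse of
A1(kappa), and a warning is raised when the pooled resultant drops below
0.45, outside the test's validity range. Simulation tests pin its type-I
error to [0.03, 0.07] at alpha = 0.05. Welch's t (from summary statistics,
Welch--Satterthwaite df) handles sex comparisons, and a chi-square
goodness-of-fit with proportional expected weights tests whether meal counts
are proportionate to the number of contributing subjects per day type.

## The synthetic world

The generator emulates the cohort's structure with fixed defaults; they were
chosen once, from the published summary scale, and are not tuned to test
outcomes:

* **Rosters**: a 35-day cycle using the full shift catalogue (0700--1600,
  0700--1900 morning; 1500--2400 evening; 2230--0730, 2300--0800, 1900--0700
  night) with runs of >= 3 consecutive shifts, and a 28-day cycle of 12-h
  day and night shifts; in a mixed cohort one subject in eight works the
  28-day cycle (the cohort's 27:4 split).
* **Sleep**: day-type-conditional wake/onset means and SDs (rest
  0800/2256, morning 0532/2215, evening 0834/0111+1d, night 1558/0914+1d;
  SDs 7--39 min treated as between-day SDs -- the source does not
  distinguish SD from SEM). Implied durations outside 2.5--16 h, which
  arise at rest-to-night and night-to-rest transitions, fall back to 7 h or
  9 h sleeps; first-in-run night days therefore have long (~32 h) but valid
  windows. Mean day lengths of *interior* days (previous and next day the
  same type -- the analogue of the cohort's second-in-sequence collection
  days) fall in the published 23.4--24.6 h band; run-boundary days do not,
  and tests select accordingly.
* **Meals**: counts are Poisson + 1 with day-type means 7.5/6.3/5.0/5.9;
  times come from von Mises mixtures dominated by a 1600--2000 h component
  on every day type, with a 0200 h component of weight 0.30 on night-shift
  days (mirroring the published ~30% nocturnal intake); sizes are lognormal
  at the published %BMR scale; macronutrient shares are Dirichlet with
  alpha proportional to (44, 36, 18); sugar and saturated-fat fractions are
  Beta around 0.37 and 0.33; alcohol kcal is 0 (no alcohol values are
  published). Mixture sampling is restricted to the wake period by
  rejection; this truncation slightly biases realized mean times away from
  the component mu, so parameter-recovery tests compare pipeline estimates
  against the *ground-truth stream* (exactly recomputable from the emitted
  records) and allow a small extra margin against mu.
* **Merge/filter exercise**: 15% of meals are emitted as two same-type
  records 3--12 min apart (conserving totals) and 10% are downgraded to
  low-kcal beverage-only records, so the 15-min merge and >5 kcal filter
  operate on realistic input.

What a green test does *not* establish: the generator draws meal times
independently given the day type (no within-day appetite dynamics, no
activity--intake coupling -- the source reports activity but no model
linking it to intake), timestamps are timezone-naive local times (no DST),
and photograph-level nutrient estimation is out of scope (kcal and macros
are emitted directly). Group-level published results (exact %BMR values,
circular means of 2308 h vs 1525 h) are properties of the real cohort's
undeposited raw data and are *not* reproduction targets; the synthetic
world reproduces their direction and scale, and the tests assert exactly
that.

## Numerical choices

Half-open bin and night-window boundaries; closed work intervals; strict
>5 kcal; circular mean undefined at rho < 1e-12; von Mises sampling by the
Best--Fisher rejection algorithm (exact for kappa = 0 and degenerate for
very large kappa); kappa inversion tolerance follows the three-piece
approximation's accuracy. Windows at (12, 36) h bounds, BMR plausibility
warnings at 800--4000 kcal. All randomness flows through R's session RNG so
a single seed fixes the entire artifact; exports are byte-identical under a
fixed seed.
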