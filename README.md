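# chrononutr

Chrononutrition analysis of meal timing in rotating-shift workers.

Shift workers eat on schedules set by their rosters, and the *timing* of
their caloric intake — more than its quantity or composition — is an
emerging risk factor for metabolic disease. `chrononutr` is for
chronobiology and occupational-health researchers who have three event
streams per subject (a timestamped meal log with kcal and macronutrient
kcal, a work log of shift start/end times, and a sleep log of
onset/wake intervals) and want the full analysis:

* **Intake events** — same-type meal records within 15 min merge (chained)
  into one event at the last timestamp; kcal and macros are conserved
  exactly.
* **Day windows** — shifts are classified as morning (start 0500–0900 h),
  evening (end 2200–0200 h) or night (covering all of 0100–0500 h), with
  durations outside 4.5–13.5 h excluded; analysis days run wake-to-wake
  around the main (longest) sleep of each day.
* **Metrics per subject-day** — intake as % of Mifflin–St Jeor BMR
  weighted by day length, `100·kcal/(BMR·L/24)`; first-meal latency and
  eating window on nap-adjusted time awake; the kcal-weighted circular
  mean intake time and mean resultant length
  `rho = |Σ wᵢ e^{iθᵢ}| / Σ wᵢ`, `θᵢ = 2π hᵢ/24`, with circular SD
  `√(−2 ln rho)·24/2π`; percent of kcal at night (2300–0600 h) and at
  work; 4-h clock-time and time-awake caloric distributions.
* **Statistics** — χ² goodness of fit with proportional expected weights,
  Welch's t from summaries, the Watson–Williams circular ANOVA
  `F = c·(N−k)(ΣRᵢ−R) / ((k−1)(N−ΣRᵢ))`, linear mixed-effects day-type
  models (`lme4`, sex/age covariates, subject random intercept) with
  pairwise contrasts, and Benjamini–Hochberg adjustment within table
  families.
* **Synthetic data** — a generator for 35- and 28-day rosters with the
  field-realistic shift catalogue, day-type-conditional sleep timing, von
  Mises meal-time mixtures (nocturnal component on night-shift days),
  lognormal calories and Dirichlet macros, with exact ground truth.

See `vignettes/chrononutrition-methods.Rmd` for the model, assumptions
and design choices.

## Worked example

```r
library(chrononutr)
cfg <- pipeline_config(simulate = generator_config(n_subjects = 6, seed = 42),
                       seed = 42)
b <- run_pipeline(cfg, out_dir = "out")   # writes CSVs + run log

round(tapply(b$metrics$total_pct_bmr, b$metrics$day_type, mean), 1)
#> evening morning   night    rest
#>   121.9   141.9   140.5   181.8

b$report$circular_table
#>         day_type  n circ_mean_h       rho circ_sd_h
#> rest        rest 89    16.36467 0.8477920  2.195059
#> morning  morning 48    15.19014 0.5843913  3.959206
#> evening  evening 34    16.64263 0.8211213  2.398129
#> night      night 36    21.54764 0.6628196  3.464181

round(tapply(b$metrics$pct_at_night, b$metrics$day_type, mean), 1)
#> evening morning   night    rest
#>     2.0     1.4    26.0     0.2
```

Reading this output: subjects eat the most relative to their metabolic
requirement on rest days (181.8 %BMR vs 121.9 on evening-shift days); the
group circular mean intake time on night-shift days (~21:33) is hours later
than on rest days (~16:22) with a smaller rho (more dispersed intake); and
night-shift days place ~26% of calories in the 2300–0600 h window versus
~0.2% on rest days. The omnibus day-type tests land in
`b$stats$results` — e.g. the circular ANOVA here gives
`F(3, 203) = 29.0, p < 1e-15` — and pairwise contrasts in
`b$stats$contrasts`.

Single functions work standalone:

```r
mifflin_st_jeor("male", 32, 180, 80)            # 1770 kcal/day
circular_summary(c(8, 20), weights = c(300, 600))
#> Weighted circular summary: mean 20:00, rho 0.333, SD 5.66 h (n=2, weight=900)
chi_square_gof(c(210, 133, 85, 141), c(28, 21, 17, 24))
#> Chi-square goodness of fit: statistic = 11.6, df = (3), p = 0.008858
```

## Command line

```sh
Rscript inst/exec/chrononutr simulate --seed 7 --out data/      # synthetic CSVs
Rscript inst/exec/chrononutr run --config config.json --seed 7 --out out/
```

`config.json` may point at the four input CSVs (`meals`, `work`, `sleep`,
`subjects`) or contain a `simulate` block; thresholds (`min_kcal`,
`night_window`, shift-duration bounds, bin width) all default to the
standard analysis values.

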