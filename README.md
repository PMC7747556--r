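# actiFLM

Functional linear modeling of 24-hour rest–activity rhythms from
collar-mounted accelerometer counts in companion dogs.

## The problem

Activity monitors worn on a dog's collar record an integer activity count
per 1-minute epoch — 1440 points a day, typically for 14 days. Classic
summaries (total daily counts, day/night means) answer *how much* dogs
move, but not *when* covariate effects act across the day. `actiFLM`
implements both analyses for such records:

* **Pointwise functional linear model (FLM).** Each dog's record is
  averaged into a 1440-minute diurnal profile and smoothed with a
  truncated Fourier series on the 24-h period,
  `y_i(t) = a_0 + Σ_k [a_k cos(2πkt/24) + b_k sin(2πkt/24)]`. At every
  clock minute an F statistic compares the smoothed activity functions
  across a covariate (age, sex, body mass),
  `F(t) = [(SSE_0(t) − SSE_1(t))/q] / [SSE_1(t)/(n − p)]`, and a
  permutation test (subject-to-covariate assignments shuffled, 500
  permutations, α = 0.05 by default) yields a pointwise critical-value
  curve. Minutes where the observed F exceeds the critical curve are where
  groups differ; they are reported as clock-time intervals.
* **Day/night mixed models with model averaging.** Log mean day- and
  nighttime activity (night = owner-reported bedtime to waketime) is
  modelled as `log(activity) ~ day type + age + sex + mass + (1 | dog)`
  by maximum likelihood; all 16 fixed-term subsets are ranked by AIC,
  candidates with ΔAIC < 10 retained, and conditional (natural)
  model-averaged coefficients reported with unconditional SEs, z values
  and 95% CIs.
* **Synthetic cohort generator.** Cohorts with a bimodal diurnal template
  (peaks ≈ 07:00 and 19:00, midday lull, deep overnight trough), per-dog
  covariates and random activity levels, weekend daytime modulation,
  time-windowed covariate effects, overdispersed negative-binomial counts
  and optional collar-off gaps — ground truth for validating the whole
  pipeline.

The methods vignette (`vignettes/actigraphy-flm-methods.Rmd`) documents
the model, the design decisions and the package's own calibration and
recovery studies.

## Worked example

```r
library(actiFLM)

cohort <- simulateCohort(simConfig(), seed = 42)   # 42 dogs x 14 days
cohort
#> ActivityCohort: 42 subjects ( 21 F / 21 M )
#>   recordings: 14.0-14.0 days; diary: 588 nights; truth: yes

curves <- evaluateCurves(
  lapply(series(cohort), function(s) fourierFit(averageDailyProfile(s))),
  colData = subjects(cohort))

res <- permutationTest(curves, "age", nPermutations = 500, seed = 99)
res
#> FLMResult for 'age': 1440 grid minutes, 500 permutations, alpha 0.05
#>   358 minutes significant (24.9% of grid)
#>   intervals: 00:28-01:07 (39 min), 01:36-02:04 (28 min), 07:36-09:24 (108 min),
#>              18:15-20:20 (125 min), 22:36-22:50 (14 min), 23:13-23:57 (44 min)
```

The generator's default cohort injects an age effect inside the morning
(07–10 h) and evening (17:30–21 h) activity peaks, and the FLM localizes
it there: the two dominant significant intervals, 07:36–09:24 and
18:15–20:20, sit inside the injected windows (younger dogs more active
during the peaks). The day/night mixed models on the same cohort:

```r
summaries <- do.call(rbind, lapply(subjects(cohort)$id, function(id) {
  d <- diaries(cohort)
  labs <- classifyDayNight(series(cohort, id), d[d$id == id, , drop = FALSE])
  summarizeActivity(series(cohort, id), labs)
}))
tab <- buildSummaryTable(summaries, subjects(cohort))
dredgeAndAverage(tab, "daytime")
#> ModelAverageResult (daytime activity): 8 retained of 16 candidate models
#>                     Estimate (SE) z value p value        95% CI
#> Day type (weekend)  0.176 (0.003)  53.869 < 0.001  0.170, 0.183
#> Age                -0.075 (0.041)   1.843   0.065 -0.156, 0.005
#> Sex (male)          0.032 (0.083)   0.385   0.700 -0.131, 0.196
#> Body mass           0.023 (0.042)   0.552   0.581 -0.059, 0.104
```

The day-type estimate, 0.176 on the log scale, recovers the simulated
weekend daytime multiplier (log 1.2 ≈ 0.182): dogs are ~20% more active
by day on weekends. The peak-confined age effect is strongly visible to
the FLM but, diluted over the whole daytime window, only marginal in the
day-level model — exactly the contrast between the two analyses.

`runPipeline(runConfig(...))` chains simulate → validate → smooth → flm →
lmm and writes TSV artifacts, figure PNGs and a markdown report; a thin
command-line wrapper with the same stages as subcommands is in
`inst/scripts/actiflm-cli.R`.

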