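---
title: "Functional linear modeling of companion-dog actigraphy: methods and design"
author: "actiFLM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Functional linear modeling of companion-dog actigraphy: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7,
                      fig.height = 4.5)
library(actiFLM)
```

## The problem

Collar-mounted accelerometers summarize a dog's gross motor activity as an
integer count per 1-minute epoch, 1440 points per day, typically worn for
two weeks. Two complementary questions arise from such records:

1. **When during the 24-h day** does a covariate (age, sex, body mass, day
   type) change activity? Summaries like "total daily counts" throw the
   timing away; the answer needs the activity *curve*.
2. **How much** does average day- and nighttime activity change with those
   covariates, accounting for the repeated measurement of each dog?

`actiFLM` implements both analyses — a pointwise functional linear model
(FLM) with a permutation critical-value curve for question 1, and
log-linear mixed models with all-subsets AIC conditional model averaging
for question 2 — together with a synthetic cohort generator that provides
ground truth for validating every stage.

## The synthetic cohort generator

No public dataset accompanies this class of study, so the package treats
simulation as a first-class module. `simulateCohort()` draws, per dog,

* covariates: ages uniform on 2–9 years, masses uniform on 2.7–45.4 kg,
  sexes balanced F/M — matching a typical healthy-adult companion-dog
  cohort (mean age ≈ 5.5 y, mean mass ≈ 24 kg);
* a habitual bedtime in 22:00–23:00 and waketime in 06:00–08:00 (owners'
  reported norms), jittered ±30 min per night in the diary to exercise
  diary parsing;
* a per-dog random log-rate intercept, N(0, 0.3²) by default — dogs differ
  substantially in overall activity level;
* counts per minute from a negative binomial around the latent mean.
  Actigraphy counts are overdispersed, so Poisson noise would be
  unrealistically clean; the NB size parameter defaults to 1.5 and is
  exposed in the configuration because within-dog dispersion is not
  reported in the literature this emulates — it is a placeholder a user
  should calibrate to their own monitors.

The latent mean is a **bimodal diurnal template**: two wrapped-Gaussian
bumps (07:00 and 19:00, SD 1.5 h, height 220 counts/min) over a day/night
step baseline (80 counts/min by day, 5 by night, night span 22:00–07:00).
This reproduces the canonical companion-dog pattern: morning and evening
activity peaks tied to the owner's schedule, a midday lull that stays well
above the overnight trough. On weekends the daytime portion is multiplied
by 1.2 (owner-driven activity rises on non-work days; night activity does
not).

```{r template}
cfg <- simConfig()
t <- seq(0, 24, by = 1/60)
plot(t, diurnalTemplate(cfg, t), type = "l", lwd = 2,
     xlab = "clock hour", ylab = "latent rate (counts/min)")
```

Covariate effects are injected **multiplicatively on the log rate** inside
configurable clock windows, so the downstream log-linear mixed model is
correctly specified by construction. The default effect set mirrors what a
healthy-adult cohort shows: age dampens activity during the two peaks
(−0.08/yr in 07–10 h and 17:30–21 h), males are less active through the
evening (−0.30 in 18–24 h), lighter dogs stir briefly after midnight
(−0.01/kg in 0–1 h). Within a window the effect follows a raised-cosine
(Hann) taper by default — effects wax and wane smoothly rather than
switching on — with flat and tapered-plateau (`"tukey"`) shapes available.
Outside its window an effect is exactly zero, which makes localisation
testable on the latent mean.

Collar-off time is represented as *missing*, never as zero counts: a zero
is a still dog, an absent record is no information. `applyGaps()` masks
whole days or multi-hour spans; all downstream averages skip masked
epochs, and a stratum-day with more than half its window missing is
dropped rather than summarized. Whether the original studies excluded
collar-off spans or zero-filled them is generally unstated; the explicit
missing marker is this package's policy and is surfaced in the QC report.

What the generator does **not** emulate: raw tri-axial accelerations or
count-conversion firmware (epoch counts are the atomic unit), serial
correlation of counts within a day beyond the diurnal mean, behavioral
feedback between dogs and owners, or seasonal change across the two weeks.
Passing tests therefore demonstrate correctness of the statistical
machinery under a realistic marginal data model, not fidelity to any
particular monitor.

## From epochs to curves

`averageDailyProfile()` collapses a multi-day record to the per-minute
across-day mean (per clock minute, over non-missing epochs), and
`fourierFit()` projects that 1440-point profile onto the periodic basis

$$\{1,\ \cos(2\pi k t/24\mathrm{h}),\ \sin(2\pi k t/24\mathrm{h})\},
\qquad k = 1, \dots, K,$$

by ordinary least squares on the observed minutes. Missing minutes are
excluded rather than imputed — the basis interpolates through gaps. The
fit is a plain truncated Fourier series with no roughness penalty;
penalized or B-spline variants are deliberately out of scope.

**Choosing K.** The default is K = 9 (19 coefficients): a 24-h day with
two peaks, two shoulders and a nocturnal trough has its energy in the
first handful of harmonics, and K = 9 tracks that shape without chasing
minute-level noise. One genuine constraint matters when the *question* is
localisation: a feature of width w hours needs harmonics up to roughly
24/w to be represented, and asking the model about a ~3 h window with a
K = 9 basis (resolution ≈ 24/9 ≈ 2.7 h) leaves truncation ringing spread
across the whole day. The package's own effect-recovery study (below)
therefore smooths at K = 30; any user probing sub-3-h structure should
raise K accordingly. Smoothing is applied to the across-day average
profile, one curve per dog; a per-day curve mode is out of scope.

`evaluateCurves()` assembles the cohort into a `CurveMatrix` — a
`SummarizedExperiment` with grid minutes as rows, subjects as columns and
covariates in `colData`. Raw basis evaluations can dip below zero between
observed points; they are kept as-is for inference and floored at zero
only in plots.

## The pointwise permutation F-test

At every grid minute t, `pointwiseF()` regresses the subjects' smoothed
values y_i(t) on a design with intercept and the covariate under test
(continuous covariates as a 1-df slope, factors via treatment contrasts),
and forms

$$F(t) = \frac{(SSE_0(t) - SSE_1(t))/q}{SSE_1(t)/(n - p)},$$

the classical partial F; for a two-level factor this is exactly one-way
ANOVA. `permutationTest()` then rebuilds the null distribution of F(t) by
shuffling the assignment of covariate values to subjects. Design choices:

* **The whole subject curve is the exchangeable unit.** Under the null of
  no covariate effect, subjects' curves are exchangeable; permuting within
  a curve or within days would break the within-curve dependence and is
  never done.
* **The observed assignment is included as permutation 1 of B.** This
  bounds every pointwise p-value below by 1/B and makes the pointwise
  rejection probability exactly α under the null (the observed F is
  exchangeable with the B−1 sampled ones, so it exceeds the ⌈(1−α)B⌉-th
  order statistic of the pooled set with probability exactly
  ⌊αB⌋/B = 0.05 at the defaults).
* **Critical curve and significance.** At each minute the critical value
  is the empirical ⌈(1−α)B⌉-th order statistic of the B permutation F
  values; a minute is significant when the observed F is *strictly above*
  it. `significantIntervals()` merges significant minutes into maximal
  clock intervals, wrapping midnight.
* **One covariate at a time by default.** Published FLM panels test age,
  mass and sex in separate displays; adjusted designs are supported
  (`adjust =`), in which case only the tested covariate's column is
  permuted against the rest (a simple-permutation scheme, documented as an
  approximation; `permuteAll = TRUE` permutes the full design).
* **Seeds.** The permutation stream takes its own seed, kept separate from
  the cohort seed in every built-in experiment: reusing one integer for
  both would make the sampled permutations a deterministic function of the
  data.

The defaults — 500 permutations, α = 0.05, 1440-minute grid — are
configuration values, not constants, and the run report records them.

```{r flm-demo}
co <- simulateCohort(simConfig(nSubjects = 12, nDays = 7), seed = 3)
curves <- evaluateCurves(
  lapply(series(co), function(s) fourierFit(averageDailyProfile(s))),
  grid = seq(0, 1430, by = 10), colData = subjects(co))
res <- permutationTest(curves, "age", nPermutations = 200, seed = 1)
res
plotFLM(curves, res)
```

### What the calibration and recovery studies show

Two package-level experiments characterize the test (both are run in the
test suite; the null calibration is also what `scripts/acceptance.R`
recomputes):

**Null calibration.** Replicate 40-dog cohorts with all covariate effects
zero and no between-dog level variation (count noise only); the mean
fraction of grid minutes declared significant at α = 0.05 sits at the
nominal 0.05. The count-noise-only null isolates what the experiment
estimates: pointwise validity holds under between-dog heterogeneity too
(exchangeability is all the test needs), but a multiplicative random
level makes F(t) nearly perfectly correlated across minutes, so the
"fraction significant" in any one replicate becomes all-or-nothing and an
experiment of a few dozen replicates no longer pins down its mean. With
count noise only, K = 9 smoothing leaves ≈ 19 effective degrees of
freedom across the grid and a 100-replicate mean carries a Monte-Carlo SE
of ≈ 0.005.

**Effect localisation.** A tapered-plateau (tukey, taper 0.15) age effect
of −0.12/yr confined to the 07–10 h and 17:30–21 h peak windows, cohorts
otherwise at defaults (including the 0.3-SD random level), smoothing at
K = 30. Averaged over 10 replicate cohorts, ≈ 86% of window minutes are
declared significant and ≈ 5% of outside minutes. The three experiment
parameters are not arbitrary: the basis must resolve the ~30-min effect
shoulders (hence K = 30 — at the default K = 9 the truncated projection
of *any* strictly windowed effect rings across the whole day, and against
the tiny overnight noise floor those ripples are declared significant far
above α); the plateau keeps near-full amplitude over most of the window
(a Hann bump's soft edges cap inside power near 70%); and the amplitude
puts the detection threshold between the smoothed shoulder's outside tail
and its inside flank, so transitions localize at the window edges.

## Day/night mixed models with model averaging

`classifyDayNight()` stratifies each epoch by the owner diary: night is
the half-open window [bedtime, waketime) on the circular clock, attributed
to the calendar date of the bedtime; the date's daytime is its complement
(waketime to bedtime). Diary gaps fall back to a 22:00–07:00 default with
a warning; a missing waketime defaults to bedtime + 9 h. Weekend =
Saturday/Sunday. `summarizeActivity()` yields one day- and one night-mean
per dog-date over non-missing epochs (dropped if more than half the
stratum window is missing or unrecorded), and `buildSummaryTable()` takes
log(mean + 1) — day means are positively skewed, and the +1 offset keeps
all-zero night strata finite — storing centered/scaled copies of age and
mass alongside the raw values.

`fitRandomInterceptModel()` fits, per stratum,

$$\log(\text{activity}) \sim \text{day type} + \text{age} + \text{sex} +
\text{mass} + (1 \mid \text{dog}),$$

and every subset of the four fixed terms, by **maximum likelihood** (not
REML: AIC values are only comparable across fixed-effect structures under
ML). Singular fits (intercept variance at the boundary) are flagged, not
errors. `dredgeAndAverage()` ranks the 16 candidates by AIC, retains
ΔAIC < 10, weights them by w ∝ exp(−Δ/2), and reports **conditional
(natural) averages**: each term averaged only over retained models that
contain it, with weights renormalized over those models, the unconditional
SE including between-model variance,

$$SE = \sqrt{\textstyle\sum_m w_m\,(se_m^2 + (\beta_m - \bar\beta)^2)},$$

z = |estimate|/SE against a standard normal, and CI = estimate ± 1.96 SE.
The full (zero-substituted) average is reported alongside in the
candidate-model table, which is the "shrinkage" counterpart: conditional
estimates answer "how big is the effect where it is included", full
averages shrink rarely-selected terms toward zero. AICc is available via
argument for small samples, with plain AIC as the default convention.

Two conventions worth flagging. First, z-based Wald intervals from an ML
mixed model are known to run slightly narrow for between-subject terms at
a few dozen subjects (no Satterthwaite/Kenward-Roger correction is
applied, matching the z-value reporting convention of standard
model-averaging software); the package's recovery study measures pooled
coverage ≈ 0.92 at 42 dogs. Second, the response is the per-day *mean*
over non-missing epochs, not the daily total; the two differ by a
day-length factor that the log intercept absorbs unless missingness
varies systematically within strata.

```{r lmm-demo}
summaries <- do.call(rbind, lapply(subjects(co)$id, function(id) {
  d <- diaries(co)
  labs <- suppressWarnings(
    classifyDayNight(series(co, id), d[d$id == id, , drop = FALSE]))
  summarizeActivity(series(co, id), labs)
}))
tab <- buildSummaryTable(summaries, subjects(co))
dredgeAndAverage(tab, "daytime")
```

## Numerical and degenerate-input policy

* All clock arithmetic uses minutes-since-midnight integers and half-open
  intervals; timestamps are UTC, so daylight-saving shifts never corrupt
  the 1440-minute grid.
* Epoch CSV ingestion errors on non-monotone or duplicated timestamps
  (naming the first offender), fills grid holes with missing-marked
  epochs, and auto-detects a units row under the header.
* `pointwiseF()` classifies degenerate grid points against the total
  across-subject variation: no variation at all gives F = 0; genuine
  variation fitted exactly gives F = +Inf with a warning. Rank-deficient
  designs are rejected naming the collinear columns.
* The Fourier fit requires at least 2K+1 observed minutes and reports the
  residual sum of squares; fitting fitted values reproduces the
  coefficients (it is a projection), and RSS is non-increasing in K.
* Every stochastic function takes an explicit seed and restores the
  caller's RNG state; identical (configuration, seed) pairs give
  byte-identical artifacts, and the pipeline derives per-stage seeds from
  one root seed.

## Problem sizes used in the built-in studies

The validation studies run at the cohort scale they describe: 40–42
subjects × 14 days × 1440 epochs. The null-calibration study uses 100
replicate cohorts on a 144-point grid with 500 permutations; the
localisation study 10 replicate cohorts on the full 1440-point grid; the
mixed-model recovery study 100 replicate summary tables (the
dredge-and-average stage operates on summary tables, so it is exercised
directly at that level). These sizes put each study's Monte-Carlo error
well inside the margins it asserts.

## Known limitations

* Pointwise inference only: no max-F global band by default (available as
  an option), no FDR control across minutes — intervals are descriptive
  of where the pointwise test rejects.
* The simple-permutation scheme for adjusted designs is approximate
  (Freedman–Lane-style schemes are not implemented).
* No functional random effects, curve registration, or
  function-on-function regression; between-dog phase differences widen
  group bands rather than being aligned away.
* The generator's dispersion and between-dog variance defaults are
  placeholders in the absence of published values; both are configuration
  fields.
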