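# S4 classes for the actigraphy analysis pipeline.

#' @include AllGenerics.R utils.R
NULL

#' Time-windowed covariate effect on the latent activity rate
#'
#' Describes how one cohort covariate perturbs the log activity rate as a
#' function of clock time: within the half-open clock window `window`
#' (hours, may wrap midnight) the log rate is shifted by
#' `slope * taper(t) * x`, where `x` is the (centered) covariate value and
#' `taper` is one of: a raised-cosine (Hann) bump peaking at the window
#' centre (`shape = "hann"`), a flat indicator (`shape = "flat"`), or a
#' tapered plateau (`shape = "tukey"`: full effect over the central half
#' of the window with cosine shoulders over the outer quarters). The
#' effect is exactly zero outside the window and 24-h periodic by
#' construction.
#'
#' @slot covariate one of `"age"`, `"sex"`, `"mass"`, `"day_type"`.
#' @slot slope log-rate change per covariate unit at the taper maximum.
#' @slot window numeric length-2, clock hours `[from, to)`.
#' @slot shape `"hann"`, `"flat"` or `"tukey"`.
#' @slot taper shoulder fraction of the `"tukey"` shape (default 0.25).
#' @export
setClass("CovariateEffect",
  representation(covariate = "character", slope = "numeric",
                 window = "numeric", shape = "character", taper = "numeric"),
  prototype(shape = "hann", taper = 0.25))

setValidity("CovariateEffect", function(object) {
  msg <- character()
  if (!object@covariate %in% c("age", "sex", "mass", "day_type"))
    msg <- c(msg, "covariate must be one of age, sex, mass, day_type")
  if (length(object@window) != 2L || !all(is.finite(object@window)))
    msg <- c(msg, "window must be two finite clock hours")
  if (!is.finite(object@slope)) msg <- c(msg, "slope must be finite")
  if (!object@shape %in% c("hann", "flat", "tukey"))
    msg <- c(msg, "shape must be 'hann', 'flat' or 'tukey'")
  if (length(object@taper) != 1L || object@taper <= 0 || object@taper > 0.5)
    msg <- c(msg, "taper must be a single value in (0, 0.5]")
  if (length(msg)) msg else TRUE
})

#' @param covariate,slope,window,shape see slots.
#' @param taper shoulder width of the `"tukey"` plateau, as a fraction of
#'   the window at each end.
#' @rdname CovariateEffect-class
#' @export
covariateEffect <- function(covariate, slope, window, shape = "hann",
                            taper = 0.25) {
  new("CovariateEffect", covariate = covariate, slope = slope,
      window = as.numeric(window), shape = shape, taper = taper)
}

#' Configuration of the synthetic actigraphy cohort generator
#'
#' Holds every knob of the simulator: cohort size and duration, the bimodal
#' diurnal template (two wrapped-Gaussian activity bumps over a day/night
#' step baseline), covariate ranges, injected time-windowed covariate
#' effects, between-dog variation, count overdispersion and collar-off gaps.
#' Defaults emulate a two-week companion-dog actigraphy study: 42 dogs wear
#' monitors for 14 days of 1-min epochs; activity peaks near 07:00 and
#' 19:00 with a midday lull and a deep overnight trough; owners go to bed
#' between 22:00 and 23:00 and rise between 06:00 and 08:00.
#'
#' @slot nSubjects number of dogs.
#' @slot nDays days of recording per dog.
#' @slot epochMinutes epoch length in minutes (must divide 1440).
#' @slot peakTimes clock hours of the morning/evening activity peaks.
#' @slot peakWidths wrapped-Gaussian SD of each peak, hours.
#' @slot peakHeights peak amplitude above baseline, counts/epoch.
#' @slot baselineDay,baselineNight step-baseline rates, counts/epoch.
#' @slot nightSpan clock hours `[from, to)` of the template's night step.
#' @slot weekendDayMultiplier multiplies the daytime latent rate on Sat/Sun.
#' @slot effects list of [CovariateEffect] objects.
#' @slot randomInterceptSD SD of the per-dog log-rate intercept.
#' @slot dispersion negative-binomial size parameter (> 0; larger = closer
#'   to Poisson).
#' @slot gapRate per-day probability that a day is masked as collar-off.
#' @slot ageRange,massRange uniform sampling ranges for age (years) and
#'   body mass (kg).
#' @slot bedtimeRange,waketimeRange clock-hour ranges for per-dog habitual
#'   bed and wake times; each night's diary entry jitters them by up to
#'   +/- `diaryJitterMinutes`.
#' @slot diaryJitterMinutes per-night jitter half-width, minutes.
#' @slot startDate first calendar day of recording.
#' @export
setClass("SimConfig",
  representation(
    nSubjects = "integer", nDays = "integer", epochMinutes = "integer",
    peakTimes = "numeric", peakWidths = "numeric", peakHeights = "numeric",
    baselineDay = "numeric", baselineNight = "numeric", nightSpan = "numeric",
    weekendDayMultiplier = "numeric", effects = "list",
    randomInterceptSD = "numeric", dispersion = "numeric",
    gapRate = "numeric", ageRange = "numeric", massRange = "numeric",
    bedtimeRange = "numeric", waketimeRange = "numeric",
    diaryJitterMinutes = "numeric", startDate = "Date"))

setValidity("SimConfig", function(object) {
  msg <- character()
  num <- c(object@peakTimes, object@peakWidths, object@peakHeights,
           object@baselineDay, object@baselineNight, object@nightSpan,
           object@weekendDayMultiplier, object@randomInterceptSD,
           object@dispersion, object@gapRate)
  if (!all(is.finite(num))) {
    return("all numeric parameters must be finite")
  }
  if (object@nSubjects < 2L) msg <- c(msg, "nSubjects must be >= 2")
  if (object@nDays < 1L) msg <- c(msg, "nDays must be >= 1")
  if (object@epochMinutes < 1L || MINUTES_PER_DAY %% object@epochMinutes != 0L)
    msg <- c(msg, "epochMinutes must divide 1440")
  if (any(object@peakHeights < 0) || object@baselineDay < 0 ||
      object@baselineNight < 0)
    msg <- c(msg, "peak and baseline rates must be >= 0")
  if (any(object@peakWidths <= 0)) msg <- c(msg, "peakWidths must be > 0")
  if (object@dispersion <= 0) msg <- c(msg, "dispersion must be > 0")
  if (object@gapRate < 0 || object@gapRate > 1)
    msg <- c(msg, "gapRate must be in [0, 1]")
  if (!all(vapply(object@effects, is, logical(1), class2 = "CovariateEffect")))
    msg <- c(msg, "effects must be a list of CovariateEffect objects")
  if (length(msg)) msg else TRUE
})

#' Default covariate effects: what a healthy-adult-dog cohort shows
#'
#' Age dampens activity during the two activity peaks, males are less
#' active through the evening, and lighter dogs stir briefly after
#' midnight. Slopes act per centered covariate unit (years, kg, or the
#' male-vs-female contrast).
#' @rdname SimConfig-class
#' @export
defaultEffects <- function() {
  list(
    covariateEffect("age", slope = -0.08, window = c(7, 10)),
    covariateEffect("age", slope = -0.08, window = c(17.5, 21)),
    covariateEffect("sex", slope = -0.30, window = c(18, 24)),
    covariateEffect("mass", slope = -0.01, window = c(0, 1))
  )
}

#' @param nSubjects,nDays,epochMinutes,peakTimes,peakWidths,peakHeights
#'   see slots.
#' @param baselineDay,baselineNight,nightSpan,weekendDayMultiplier,effects
#'   see slots.
#' @param randomInterceptSD,dispersion,gapRate,ageRange,massRange see slots.
#' @param bedtimeRange,waketimeRange,diaryJitterMinutes,startDate see slots.
#' @rdname SimConfig-class
#' @export
simConfig <- function(nSubjects = 42L, nDays = 14L, epochMinutes = 1L,
                      peakTimes = c(7, 19), peakWidths = c(1.5, 1.5),
                      peakHeights = c(220, 220), baselineDay = 80,
                      baselineNight = 5, nightSpan = c(22, 7),
                      weekendDayMultiplier = 1.2, effects = defaultEffects(),
                      randomInterceptSD = 0.3, dispersion = 1.5,
                      gapRate = 0, ageRange = c(2, 9),
                      massRange = c(2.7, 45.4), bedtimeRange = c(22, 23),
                      waketimeRange = c(6, 8), diaryJitterMinutes = 30,
                      startDate = as.Date("2020-01-06")) {
  new("SimConfig",
      nSubjects = as.integer(nSubjects), nDays = as.integer(nDays),
      epochMinutes = as.integer(epochMinutes), peakTimes = peakTimes,
      peakWidths = peakWidths, peakHeights = peakHeights,
      baselineDay = baselineDay, baselineNight = baselineNight,
      nightSpan = nightSpan, weekendDayMultiplier = weekendDayMultiplier,
      effects = effects, randomInterceptSD = randomInterceptSD,
      dispersion = dispersion, gapRate = gapRate, ageRange = ageRange,
      massRange = massRange, bedtimeRange = bedtimeRange,
      waketimeRange = waketimeRange, diaryJitterMinutes = diaryJitterMinutes,
      startDate = as.Date(startDate))
}

#' One subject's epoch-count activity record
#'
#' A strictly consecutive sequence of fixed-length epochs starting at
#' `start`, with nonnegative integer counts and an explicit missingness
#' mask (collar-off spans are *missing*, never zero).
#'
#' @slot subjectId subject identifier.
#' @slot start POSIXct timestamp of the first epoch (UTC).
#' @slot epochMinutes epoch spacing, minutes.
#' @slot counts numeric vector of nonnegative integer counts (value at
#'   masked epochs is ignored).
#' @slot missing logical mask, `TRUE` where the epoch is missing.
#' @param x an `EpochSeries`.
#' @export
setClass("EpochSeries",
  representation(subjectId = "character", start = "POSIXct",
                 epochMinutes = "numeric", counts = "numeric",
                 missing = "logical"))

setValidity("EpochSeries", function(object) {
  msg <- character()
  if (length(object@counts) != length(object@missing))
    msg <- c(msg, "counts and missing must have equal length")
  obs <- object@counts[!object@missing]
  if (length(obs) && (any(!is.finite(obs)) || any(obs < 0)))
    msg <- c(msg, "observed counts must be finite and >= 0")
  if (length(obs) && any(obs != round(obs)))
    msg <- c(msg, "observed counts must be integers")
  if (length(object@epochMinutes) != 1L || object@epochMinutes <= 0)
    msg <- c(msg, "epochMinutes must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' @param subjectId,start,epochMinutes,counts,missing see slots.
#' @rdname EpochSeries-class
#' @export
epochSeries <- function(subjectId, start, counts, epochMinutes = 1,
                        missing = rep(FALSE, length(counts))) {
  if (!inherits(start, "POSIXct")) start <- as.POSIXct(start, tz = "UTC")
  new("EpochSeries", subjectId = as.character(subjectId), start = start,
      epochMinutes = as.numeric(epochMinutes), counts = as.numeric(counts),
      missing = as.logical(missing))
}

setMethod("subjectId", "EpochSeries", function(x) x@subjectId)
setMethod("activityCounts", "EpochSeries", function(x) {
  out <- x@counts
  out[x@missing] <- NA_real_
  out
})
setMethod("isMissing", "EpochSeries", function(x) x@missing)
setMethod("epochTimes", "EpochSeries", function(x) {
  x@start + (seq_along(x@counts) - 1L) * x@epochMinutes * 60
})
setMethod("length", "EpochSeries", function(x) length(x@counts))

setMethod("show", "EpochSeries", function(object) {
  n <- length(object@counts)
  cat("EpochSeries for subject", object@subjectId, "\n",
      sprintf(" %d epochs of %g min from %s (%.1f days), %d missing (%.1f%%)\n",
              n, object@epochMinutes, format(object@start, "%Y-%m-%d %H:%M", tz = "UTC"),
              n * object@epochMinutes / MINUTES_PER_DAY, sum(object@missing),
              100 * mean(object@missing)))
})

#' A cohort of activity records with metadata and bedtime diaries
#'
#' Bundles per-subject [EpochSeries] with the cohort metadata table
#' (id, age in years, sex F/M, body mass in kg, optional SNoRE score) and
#' the per-night bedtime/waketime diary. Simulated cohorts additionally
#' carry the latent truth table (random intercepts, habitual bed/wake
#' times) used to generate them.
#'
#' @slot subjects data.frame with columns id, age, sex, mass.
#' @slot seriesList named list of [EpochSeries], one per subject.
#' @slot diary data.frame with columns id, date, bedtime, waketime
#'   ("HH:MM" strings).
#' @slot truth data.frame of latent simulation quantities (0 rows for
#'   ingested cohorts).
#' @param x an `ActivityCohort`.
#' @param id subject identifier; if omitted, the full list is returned.
#' @export
setClass("ActivityCohort",
  representation(subjects = "data.frame", seriesList = "list",
                 diary = "data.frame", truth = "data.frame"))

setValidity("ActivityCohort", function(object) {
  msg <- character()
  need <- c("id", "age", "sex", "mass")
  if (!all(need %in% names(object@subjects)))
    msg <- c(msg, "subjects needs columns id, age, sex, mass")
  else {
    if (!all(names(object@seriesList) %in% as.character(object@subjects$id)))
      msg <- c(msg, "every series id needs a metadata row")
    if (any(!is.finite(object@subjects$age)) || any(object@subjects$age <= 0) ||
        any(!is.finite(object@subjects$mass)) || any(object@subjects$mass <= 0))
      msg <- c(msg, "ages and masses must be finite and positive")
    if (!all(object@subjects$sex %in% c("F", "M")))
      msg <- c(msg, "sex must be coded F/M")
  }
  if (length(msg)) msg else TRUE
})

#' @param subjects,seriesList,diary,truth see slots.
#' @rdname ActivityCohort-class
#' @export
activityCohort <- function(subjects, seriesList, diary = emptyDiary(),
                           truth = data.frame()) {
  subjects$id <- as.character(subjects$id)
  new("ActivityCohort", subjects = subjects, seriesList = seriesList,
      diary = diary, truth = truth)
}

emptyDiary <- function() {
  data.frame(id = character(), date = as.Date(character()),
             bedtime = character(), waketime = character())
}

setMethod("subjects", "ActivityCohort", function(x) x@subjects)
setMethod("series", "ActivityCohort", function(x, id) {
  if (missing(id)) return(x@seriesList)
  out <- x@seriesList[[as.character(id)]]
  if (is.null(out)) stop("no series for subject ", id, call. = FALSE)
  out
})
setMethod("diaries", "ActivityCohort", function(x) x@diary)
setMethod("cohortTruth", "ActivityCohort", function(x) x@truth)
setMethod("length", "ActivityCohort", function(x) nrow(x@subjects))

setMethod("show", "ActivityCohort", function(object) {
  cat("ActivityCohort:", nrow(object@subjects), "subjects (",
      sum(object@subjects$sex == "F"), "F /",
      sum(object@subjects$sex == "M"), "M )\n")
  if (length(object@seriesList)) {
    days <- vapply(object@seriesList, function(s)
      length(s) * s@epochMinutes / MINUTES_PER_DAY, numeric(1))
    cat(sprintf("  recordings: %.1f-%.1f days; diary: %d nights; truth: %s\n",
                min(days), max(days), nrow(object@diary),
                if (nrow(object@truth)) "yes" else "no"))
  }
})

#' Per-minute 24-hour average activity profile of one subject
#'
#' For each of the 1440 clock minutes, the mean of non-missing counts at
#' that minute across all recorded days, plus the number of days that
#' contributed. Minutes observed on no day are `NA`.
#'
#' @slot subjectId subject identifier.
#' @slot meanCounts numeric length-1440.
#' @slot nDays integer length-1440, contributing days per minute.
#' @export
setClass("DiurnalProfile",
  representation(subjectId = "character", meanCounts = "numeric",
                 nDays = "integer"))

setValidity("DiurnalProfile", function(object) {
  msg <- character()
  if (length(object@meanCounts) != MINUTES_PER_DAY ||
      length(object@nDays) != MINUTES_PER_DAY)
    msg <- c(msg, "profile must cover exactly 1440 clock minutes")
  obs <- object@meanCounts[object@nDays > 0L]
  if (length(obs) && (anyNA(obs) || any(obs < 0)))
    msg <- c(msg, "defined mean counts must be nonnegative")
  if (any(is.na(object@meanCounts) != (object@nDays == 0L)))
    msg <- c(msg, "meanCounts must be NA exactly where nDays is 0")
  if (length(msg)) msg else TRUE
})

setMethod("subjectId", "DiurnalProfile", function(x) x@subjectId)

setMethod("show", "DiurnalProfile", function(object) {
  cat("DiurnalProfile for subject", object@subjectId, "\n",
      sprintf(" %d/%d minutes defined; days contributing: %d-%d; mean %.1f counts/min\n",
              sum(object@nDays > 0L), MINUTES_PER_DAY, min(object@nDays),
              max(object@nDays), mean(object@meanCounts, na.rm = TRUE)))
})

#' Truncated Fourier representation of a 24-h periodic activity function
#'
#' Coefficients of the least-squares projection onto
#' \eqn{\{1, \cos(2\pi k t/24), \sin(2\pi k t/24)\}, k = 1..K}; evaluation
#' is exactly 24-h periodic.
#'
#' @slot subjectId subject identifier.
#' @slot intercept mean level, counts/epoch.
#' @slot cosCoefs,sinCoefs length-K harmonic coefficients.
#' @slot rss residual sum of squares of the fit.
#' @slot nObs number of non-missing minutes fitted.
#' @param x a `FourierCurve`.
#' @param minutes evaluation points, minutes since midnight (any real
#'   values; reduced modulo 1440).
#' @export
setClass("FourierCurve",
  representation(subjectId = "character", intercept = "numeric",
                 cosCoefs = "numeric", sinCoefs = "numeric",
                 rss = "numeric", nObs = "integer"))

setValidity("FourierCurve", function(object) {
  msg <- character()
  if (length(object@cosCoefs) != length(object@sinCoefs))
    msg <- c(msg, "cosCoefs and sinCoefs must have equal length")
  if (!all(is.finite(c(object@intercept, object@cosCoefs, object@sinCoefs))))
    msg <- c(msg, "coefficients must be finite")
  if (length(msg)) msg else TRUE
})

setMethod("evaluateCurve", "FourierCurve", function(x, minutes) {
  K <- length(x@cosCoefs)
  ang <- outer(2 * pi * minutes / MINUTES_PER_DAY, seq_len(K))
  drop(x@intercept + cos(ang) %*% x@cosCoefs + sin(ang) %*% x@sinCoefs)
})

setMethod("show", "FourierCurve", function(object) {
  cat(sprintf("FourierCurve (subject %s): %d harmonics, intercept %.2f, RSS %.3g on %d minutes\n",
              object@subjectId, length(object@cosCoefs), object@intercept,
              object@rss, object@nObs))
})

#' Cohort of smoothed activity curves on a common grid
#'
#' A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' with grid minutes as rows and subjects as columns; the `"activity"`
#' assay holds each subject's smoothed curve evaluated on the grid (raw
#' evaluations, which may dip below zero -- flooring at zero is a plotting
#' concern only). `colData` carries the subject covariates, `rowData` the
#' grid minute of each row.
#' @export
setClass("CurveMatrix", contains = "SummarizedExperiment")

#' Pointwise functional linear model result for one covariate
#'
#' The observed F statistic at every grid minute, the permutation
#' critical-value curve at level `alpha` (empirical order-statistic
#' \eqn{1-\alpha} quantile of the permutation F values at each minute) and
#' the pointwise p-curve (proportion of permutation F values at least as
#' large as the observed one). Minutes where the observed F exceeds the
#' critical curve are where the covariate groups differ.
#'
#' @slot covariate name of the covariate tested.
#' @slot grid grid minutes.
#' @slot observedF,critical,pvalue per-minute curves.
#' @slot nPermutations,alpha,seed permutation-test settings.
#' @param x an `FLMResult`.
#' @export
setClass("FLMResult",
  representation(covariate = "character", grid = "numeric",
                 observedF = "numeric", critical = "numeric",
                 pvalue = "numeric", nPermutations = "integer",
                 alpha = "numeric", seed = "integer"))

setValidity("FLMResult", function(object) {
  msg <- character()
  G <- length(object@grid)
  if (length(object@observedF) != G || length(object@critical) != G ||
      length(object@pvalue) != G)
    msg <- c(msg, "curves must match the grid length")
  if (any(object@observedF < 0, na.rm = TRUE))
    msg <- c(msg, "observed F must be >= 0")
  if (any(object@pvalue < 0 | object@pvalue > 1, na.rm = TRUE))
    msg <- c(msg, "pointwise p must be in [0, 1]")
  if (object@alpha <= 0 || object@alpha >= 1)
    msg <- c(msg, "alpha must be in (0, 1)")
  if (length(msg)) msg else TRUE
})

setMethod("observedF", "FLMResult", function(x) x@observedF)
setMethod("criticalCurve", "FLMResult", function(x) x@critical)
setMethod("pointwiseP", "FLMResult", function(x) x@pvalue)

setMethod("show", "FLMResult", function(object) {
  sig <- sum(object@observedF > object@critical)
  cat(sprintf("FLMResult for '%s': %d grid minutes, %d permutations, alpha %.3g\n",
              object@covariate, length(object@grid), object@nPermutations,
              object@alpha),
      sprintf(" %d minutes significant (%.1f%% of grid)\n", sig,
              100 * sig / length(object@grid)))
  iv <- significantIntervals(object)
  if (nrow(iv)) {
    cat("  intervals:", paste(sprintf("%s-%s (%d min)", iv$from, iv$to,
                                      iv$duration), collapse = ", "), "\n")
  }
})

#' Conditional model-averaged mixed-model coefficients
#'
#' Coefficient table in the style of a model-averaging summary: for each
#' predictor the conditional (natural) average estimate across retained
#' candidate models, its unconditional SE (within- plus between-model
#' variance), z value, normal-reference p value and 95% CI; plus the
#' candidate-model table (terms, AIC, delta-AIC, Akaike weight).
#'
#' @slot response `"daytime"` or `"nighttime"`.
#' @slot coefficients the per-predictor data.frame.
#' @slot models the candidate-model data.frame.
#' @param x a `ModelAverageResult`.
#' @export
setClass("ModelAverageResult",
  representation(response = "character", coefficients = "data.frame",
                 models = "data.frame"))

setMethod("coefTable", "ModelAverageResult", function(x) x@coefficients)
setMethod("candidateModels", "ModelAverageResult", function(x) x@models)

setMethod("show", "ModelAverageResult", function(object) {
  cat(sprintf("ModelAverageResult (%s activity): %d retained of %d candidate models\n",
              object@response, sum(object@models$retained), nrow(object@models)))
  tab <- object@coefficients
  out <- data.frame(
    `Estimate (SE)` = sprintf("%.3f (%.3f)", tab$estimate, tab$se),
    `z value` = sprintf("%.3f", tab$z),
    `p value` = ifelse(tab$p < 0.001, "< 0.001", sprintf("%.3f", tab$p)),
    `95% CI` = sprintf("%.3f, %.3f", tab$ci_low, tab$ci_high),
    check.names = FALSE, row.names = tab$term)
  print(out)
})
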