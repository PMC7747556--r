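# Synthetic actigraphy cohort generator.
#
# Every downstream stage is validated against cohorts produced here, where
# the diurnal template, the covariate effects and the between-dog variation
# are known exactly.

#' The bimodal diurnal activity template
#'
#' Latent activity rate (counts per epoch) as a function of clock time:
#' two wrapped-Gaussian bumps at the configured peak times over a day/night
#' step baseline. With the default configuration the curve peaks near 07:00
#' and 19:00, sags towards midday, and drops to its overnight floor inside
#' the night span.
#'
#' @param config a [SimConfig].
#' @param t clock time in hours, any real values (reduced modulo 24).
#' @return numeric vector of nonnegative rates, exactly 24-h periodic.
#' @examples
#' cfg <- simConfig()
#' t <- seq(0, 24, by = 0.25)
#' plot(t, diurnalTemplate(cfg, t), type = "l",
#'      xlab = "clock hour", ylab = "counts/min")
#' @export
diurnalTemplate <- function(config, t) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  t <- as.numeric(t) %% 24
  base <- ifelse(inClockWindow(t * 60, config@nightSpan[1] * 60,
                               config@nightSpan[2] * 60),
                 config@baselineNight, config@baselineDay)
  bumps <- 0
  for (j in seq_along(config@peakTimes)) {
    bumps <- bumps + config@peakHeights[j] *
      wrappedGaussian(t, config@peakTimes[j], config@peakWidths[j])
  }
  base + bumps
}

# Wrapped Gaussian bump on the 24-h circle, unit height at mu.
wrappedGaussian <- function(t, mu, sd_h) {
  d <- (t - mu) %% 24
  d <- pmin(d, 24 - d)          # circular distance, in [0, 12]
  exp(-d^2 / (2 * sd_h^2))
}

#' Evaluate a covariate effect's taper at clock minutes
#'
#' The per-unit log-rate perturbation contributed by `effect` at each clock
#' minute: `slope * taper`, exactly zero outside the effect's window.
#'
#' @param effect a [CovariateEffect].
#' @param minutes clock minutes since midnight.
#' @return numeric vector, log-rate slope per covariate unit.
#' @export
effectCurveValue <- function(effect, minutes) {
  minutes <- as.numeric(minutes) %% MINUTES_PER_DAY
  from <- effect@window[1] * 60
  len <- clockWindowLength(from, effect@window[2] * 60)
  inside <- inClockWindow(minutes, from, effect@window[2] * 60)
  out <- numeric(length(minutes))
  u <- ((minutes[inside] - from) %% MINUTES_PER_DAY) / len
  out[inside] <- effect@slope * switch(effect@shape,
    flat = 1,
    hann = 0.5 * (1 - cos(2 * pi * u)),
    tukey = {                          # plateau with cosine shoulders
      a <- effect@taper
      ifelse(u < a, 0.5 * (1 - cos(pi * u / a)),
             ifelse(u > 1 - a, 0.5 * (1 - cos(pi * (1 - u) / a)), 1))
    })
  out
}

# Centered covariate codings used by the generator; slopes are per year,
# per kg, or per male-vs-female / weekend-vs-weekday contrast.
centerCovariate <- function(covariate, value, config) {
  switch(covariate,
    age = value - mean(config@ageRange),
    mass = value - mean(config@massRange),
    sex = ifelse(value == "M", 0.5, -0.5),
    day_type = ifelse(value == "weekend", 0.5, -0.5),
    stop("unknown covariate: ", covariate))
}

#' Latent mean activity curve for one subject-day
#'
#' The noiseless negative-binomial mean over the 1440 clock minutes of one
#' day: template, weekend daytime modulation, per-dog random intercept and
#' all configured covariate effects combined. This is the quantity the
#' generator draws counts around; tests of effect localisation check it
#' directly.
#'
#' @param config a [SimConfig].
#' @param age,sex,mass subject covariates (years, "F"/"M", kg).
#' @param date calendar date of the day (determines weekday/weekend).
#' @param randomIntercept the subject's log-rate intercept deviation.
#' @return numeric length-1440 vector of mean counts per minute.
#' @export
latentMeanCurve <- function(config, age, sex, mass,
                            date = as.Date("2020-01-06"),
                            randomIntercept = 0) {
  minutes <- seq_len(MINUTES_PER_DAY) - 1L
  tmpl <- diurnalTemplate(config, minutes / 60)
  weekend <- isWeekend(date)
  wfac <- rep(1, MINUTES_PER_DAY)
  if (weekend) {
    daytime <- !inClockWindow(minutes, config@nightSpan[1] * 60,
                              config@nightSpan[2] * 60)
    wfac[daytime] <- config@weekendDayMultiplier
  }
  logeff <- rep(randomIntercept, MINUTES_PER_DAY)
  vals <- list(age = age, sex = sex, mass = mass,
               day_type = if (weekend) "weekend" else "weekday")
  for (e in config@effects) {
    x <- centerCovariate(e@covariate, vals[[e@covariate]], config)
    logeff <- logeff + effectCurveValue(e, minutes) * x
  }
  tmpl * wfac * exp(logeff)
}

#' Simulate an actigraphy cohort with known ground truth
#'
#' Draws per-dog covariates (ages and masses uniform over the configured
#' ranges, sexes balanced F/M), habitual bed/wake times, and a per-dog
#' log-rate random intercept; then simulates negative-binomial epoch counts
#' around each subject-day's latent mean curve. Bedtime diaries jitter each
#' night's habitual times by up to the configured half-width. If
#' `config@gapRate > 0`, whole recording days are masked as collar-off.
#'
#' Identical `(config, seed)` pairs produce identical cohorts.
#'
#' @param config a [SimConfig].
#' @param seed integer seed controlling all randomness.
#' @return an [ActivityCohort] whose truth table records every latent
#'   quantity (random intercepts, habitual bed/wake times).
#' @examples
#' cohort <- simulateCohort(simConfig(nSubjects = 4, nDays = 2), seed = 1)
#' cohort
#' @export
simulateCohort <- function(config, seed = 1L) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  withSeed(seed, {
    n <- config@nSubjects
    ids <- sprintf("dog%02d", seq_len(n))
    sex <- rep(c("F", "M"), length.out = n)
    subjects <- data.frame(
      id = ids, sex = sex,
      age = round(runif(n, config@ageRange[1], config@ageRange[2]), 1),
      mass = round(runif(n, config@massRange[1], config@massRange[2]), 1))
    subjects <- subjects[, c("id", "age", "sex", "mass")]
    truth <- subjects
    truth$randomIntercept <- rnorm(n, 0, config@randomInterceptSD)
    truth$bedtime <- minutesToClock(
      runif(n, config@bedtimeRange[1] * 60, config@bedtimeRange[2] * 60))
    truth$waketime <- minutesToClock(
      runif(n, config@waketimeRange[1] * 60, config@waketimeRange[2] * 60))

    dates <- config@startDate + seq_len(config@nDays) - 1L
    nPerDay <- MINUTES_PER_DAY %/% config@epochMinutes
    epochMin <- config@epochMinutes * (seq_len(nPerDay) - 1L)

    seriesList <- list()
    diary <- vector("list", n)
    for (i in seq_len(n)) {
      mu <- matrix(0, nPerDay, config@nDays)
      for (d in seq_len(config@nDays)) {
        full <- latentMeanCurve(config, subjects$age[i], subjects$sex[i],
                                subjects$mass[i], dates[d],
                                truth$randomIntercept[i])
        mu[, d] <- full[epochMin + 1L] * config@epochMinutes
      }
      counts <- rnbinom(length(mu), size = config@dispersion, mu = as.vector(mu))
      s <- epochSeries(ids[i],
                       as.POSIXct(paste(config@startDate, "00:00:00"), tz = "UTC"),
                       counts, epochMinutes = config@epochMinutes)
      if (config@gapRate > 0) {
        s <- applyGaps(s, config@gapRate, seed = NULL)
      }
      seriesList[[ids[i]]] <- s

      bed <- clockToMinutes(truth$bedtime[i]) +
        round(runif(config@nDays, -config@diaryJitterMinutes,
                    config@diaryJitterMinutes))
      wake <- clockToMinutes(truth$waketime[i]) +
        round(runif(config@nDays, -config@diaryJitterMinutes,
                    config@diaryJitterMinutes))
      diary[[i]] <- data.frame(id = ids[i], date = dates,
                               bedtime = minutesToClock(bed),
                               waketime = minutesToClock(wake))
    }
    activityCohort(subjects, seriesList, do.call(rbind, diary), truth)
  })
}

#' Mask collar-off gaps in an epoch series
#'
#' Marks randomly selected spans of a series as missing (never zero):
#' whole recording days (`mode = "day"`) or a contiguous 2-8 h span within
#' a day (`mode = "span"`), each day affected independently with
#' probability `gapRate`.
#'
#' @param series an [EpochSeries].
#' @param gapRate probability in `[0, 1]` that a given day is affected.
#' @param seed optional integer seed (`NULL` uses the current RNG stream).
#' @param mode `"day"` or `"span"`.
#' @return the series with its missingness mask extended.
#' @export
applyGaps <- function(series, gapRate, seed = NULL, mode = c("day", "span")) {
  mode <- match.arg(mode)
  stopifnot(gapRate >= 0, gapRate <= 1)
  if (gapRate == 0) return(series)
  withSeed(seed, {
    nPerDay <- MINUTES_PER_DAY %/% series@epochMinutes
    nDays <- ceiling(length(series) / nPerDay)
    hit <- runif(nDays) < gapRate
    miss <- series@missing
    for (d in which(hit)) {
      first <- (d - 1L) * nPerDay + 1L
      last <- min(d * nPerDay, length(series))
      if (mode == "day") {
        miss[first:last] <- TRUE
      } else {
        spanEpochs <- round(runif(1, 120, 480) / series@epochMinutes)
        startAt <- first + floor(runif(1, 0, max(1, last - first + 1L - spanEpochs)))
        miss[startAt:min(startAt + spanEpochs - 1L, last)] <- TRUE
      }
    }
    initialize(series, missing = miss)
  })
}
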