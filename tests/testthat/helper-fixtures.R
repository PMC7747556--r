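# Shared fixtures: tiny configs, hand-built series/curves, and independent
# oracles used across test files.

# Small cohort config for fast tests.
tinyConfig <- function(nSubjects = 4L, nDays = 2L, ...) {
  simConfig(nSubjects = nSubjects, nDays = nDays, ...)
}

# Clock string "HH:MM" to minutes since midnight.
clockTestMinutes <- function(hm) {
  p <- as.integer(strsplit(hm, ":")[[1]])
  p[1] * 60L + p[2]
}

isWeekendTest <- function(d) format(as.Date(d), "%u") %in% c("6", "7")

# An EpochSeries from a days x 1440 matrix of counts (rows = days),
# starting at midnight UTC.
seriesFromDays <- function(dayMatrix, id = "s1", start = "2020-01-06",
                           missing = NULL) {
  counts <- as.vector(t(dayMatrix))
  if (is.null(missing)) missing <- rep(FALSE, length(counts))
  epochSeries(id, as.POSIXct(paste(start, "00:00:00"), tz = "UTC"),
              counts, epochMinutes = 1, missing = missing)
}

# A DiurnalProfile straight from a length-1440 vector.
profileFromVector <- function(x, id = "s1", nDays = 1L) {
  new("DiurnalProfile", subjectId = id, meanCounts = as.numeric(x),
      nDays = rep(as.integer(nDays), 1440))
}

# A FourierCurve with given coefficients.
curveFromCoefs <- function(intercept, cosCoefs, sinCoefs, id = "s1") {
  new("FourierCurve", subjectId = id, intercept = intercept,
      cosCoefs = cosCoefs, sinCoefs = sinCoefs, rss = 0,
      nObs = 1440L)
}

# A CurveMatrix directly from a grid x subjects value matrix plus covariates.
curveMatrixFromValues <- function(values, grid, covariates) {
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(activity = values),
    rowData = S4Vectors::DataFrame(minute = as.numeric(grid)),
    colData = S4Vectors::DataFrame(covariates))
  new("CurveMatrix", se)
}

# Independent one-way ANOVA F oracle for a binary grouping, computed from
# group sums at one time point.
anovaFOracle <- function(y, group) {
  g <- split(y, group)
  n <- length(y); k <- length(g)
  grand <- mean(y)
  ssb <- sum(vapply(g, function(v) length(v) * (mean(v) - grand)^2, numeric(1)))
  ssw <- sum(vapply(g, function(v) sum((v - mean(v))^2), numeric(1)))
  (ssb / (k - 1)) / (ssw / (n - k))
}

# Simulate a mixed-model summary table directly from known standardized
# coefficients: truth on (day_type weekend, age_std, sexM, mass_std).
simulateLmmTable <- function(seed, truthDay, truthNight = c(0, 0, 0, 0),
                             nSubjects = 42L, nDays = 14L, sdId = 0.2,
                             sdEps = 0.35, interceptDay = 4.5,
                             interceptNight = 3) {
  set.seed(seed)
  age <- runif(nSubjects, 2, 9)
  mass <- runif(nSubjects, 2.7, 45.4)
  sex <- rep(c("F", "M"), length.out = nSubjects)
  dates <- as.Date("2020-01-06") + seq_len(nDays) - 1L
  b <- rnorm(nSubjects, 0, sdId)
  df <- expand.grid(si = seq_len(nSubjects), di = seq_len(nDays))
  day_type <- ifelse(format(dates[df$di], "%u") %in% c("6", "7"),
                     "weekend", "weekday")
  age_std <- (age - mean(age)) / sd(age)
  mass_std <- (mass - mean(mass)) / sd(mass)
  X <- cbind(day_type == "weekend", age_std[df$si], sex[df$si] == "M",
             mass_std[df$si])
  stratumRows <- function(stratum, truth, icpt) {
    data.frame(subject = sprintf("d%02d", df$si), date = dates[df$di],
               stratum = stratum,
               day_type = factor(day_type, c("weekday", "weekend")),
               log_activity = as.numeric(icpt + X %*% truth + b[df$si] +
                                           rnorm(nrow(df), 0, sdEps)),
               age = age[df$si], sex = factor(sex[df$si], c("F", "M")),
               mass = mass[df$si], age_std = age_std[df$si],
               mass_std = mass_std[df$si])
  }
  rbind(stratumRows("daytime", truthDay, interceptDay),
        stratumRows("nighttime", truthNight, interceptNight))
}

# The two peak-window age-effect configuration used in recovery studies:
# tapered-plateau effects over the morning and evening activity peaks.
peakWindowAgeEffects <- function(slope = -0.12) {
  list(covariateEffect("age", slope, c(7, 10), shape = "tukey", taper = 0.15),
       covariateEffect("age", slope, c(17.5, 21), shape = "tukey", taper = 0.15))
}

# Smooth a whole cohort into a CurveMatrix.
cohortCurves <- function(cohort, grid = seq_len(1440) - 1L, nHarmonics = 9L) {
  evaluateCurves(lapply(series(cohort), function(s)
    fourierFit(averageDailyProfile(s), nHarmonics)),
    grid = grid, colData = subjects(cohort))
}
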