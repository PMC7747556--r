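# Synthetic cohort generator: diurnal template, covariate effects, count
# noise, gaps, determinism.

test_that("diurnal template degenerates to a constant and is 24-h periodic", {
  cfg <- simConfig(peakHeights = c(0, 0), baselineDay = 7, baselineNight = 7)
  t <- seq(0, 24, by = 0.01)
  expect_equal(diurnalTemplate(cfg, t), rep(7, length(t)))

  cfg <- simConfig()
  set.seed(5)
  t <- runif(100, 0, 24)
  expect_equal(diurnalTemplate(cfg, t), diurnalTemplate(cfg, t + 24))
  expect_true(all(diurnalTemplate(cfg, t) >= 0))
})

test_that("template peaks sit at the configured peak times on a 1-min grid", {
  cfg <- simConfig()
  grid <- (0:1439) / 60
  vals <- diurnalTemplate(cfg, grid)
  morning <- grid < 12
  argmaxMorning <- grid[morning][which.max(vals[morning])]
  expect_lte(abs(argmaxMorning - cfg@peakTimes[1]) * 60, 2)
  evening <- grid >= 12
  argmaxEvening <- grid[evening][which.max(vals[evening])]
  expect_lte(abs(argmaxEvening - cfg@peakTimes[2]) * 60, 2)
  # overnight level below the midday level
  expect_lt(mean(vals[grid >= 1 & grid < 4]), mean(vals[grid >= 11.5 & grid < 13.5]))
})

test_that("invalid configurations are rejected", {
  expect_error(simConfig(nSubjects = 1), "nSubjects")
  expect_error(simConfig(epochMinutes = 7), "epochMinutes")
  expect_error(simConfig(dispersion = 0), "dispersion")
  expect_error(simConfig(baselineDay = -1), "rates")
  expect_error(simConfig(peakHeights = c(NaN, 220)), "finite")
  expect_error(covariateEffect("height", 1, c(0, 1)), "covariate")
})

test_that("each simulated subject-day holds exactly 1440 one-minute epochs", {
  co <- simulateCohort(simConfig(nSubjects = 2, nDays = 1), seed = 1)
  for (id in subjects(co)$id) {
    expect_identical(length(series(co, id)), 1440L)
  }
})

test_that("counts are nonnegative integers and generation is seed-deterministic", {
  cfg <- tinyConfig()
  co1 <- simulateCohort(cfg, seed = 9)
  co2 <- simulateCohort(cfg, seed = 9)
  co3 <- simulateCohort(cfg, seed = 10)
  s1 <- series(co1, "dog01")
  expect_true(all(s1@counts >= 0))
  expect_true(all(s1@counts == round(s1@counts)))
  expect_identical(co1@seriesList[["dog02"]]@counts,
                   co2@seriesList[["dog02"]]@counts)
  expect_identical(diaries(co1), diaries(co2))
  expect_false(identical(co1@seriesList[["dog02"]]@counts,
                         co3@seriesList[["dog02"]]@counts))

  # byte-identical CSV output under the same config + seed
  d1 <- tempfile(); d2 <- tempfile()
  writeCohort(co1, d1); writeCohort(co2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("truth table records the latent per-subject quantities", {
  co <- simulateCohort(tinyConfig(), seed = 2)
  tr <- cohortTruth(co)
  expect_setequal(c("id", "age", "sex", "mass", "randomIntercept",
                    "bedtime", "waketime"), names(tr))
  expect_identical(tr$id, subjects(co)$id)
  expect_true(all(tr$age >= 2 & tr$age <= 9))
  expect_true(all(tr$mass > 0))
})

test_that("simulated counts track the analytic latent mean", {
  # near-Poisson noise, no effects, no between-dog variation: the
  # across-day per-minute average must match the template closely
  cfg <- simConfig(nSubjects = 2, nDays = 100, effects = list(),
                   randomInterceptSD = 0, dispersion = 1e6,
                   weekendDayMultiplier = 1,
                   diaryJitterMinutes = 0)
  co <- simulateCohort(cfg, seed = 31)
  mu <- diurnalTemplate(cfg, (0:1439) / 60)
  days <- rbind(matrix(series(co, "dog01")@counts, 100, 1440, byrow = TRUE),
                matrix(series(co, "dog02")@counts, 100, 1440, byrow = TRUE))
  m <- colMeans(days)
  se <- sqrt((mu + mu^2 / 1e6) / 200)
  withinThree <- abs(m - mu) <= 3 * se
  # pointwise 3-SE bands fail ~0.3% of minutes by construction
  expect_gte(mean(withinThree), 0.99)
  expect_lt(max(abs(m - mu) / se), 5)
})

test_that("covariate effects are zero outside their windows on the latent mean", {
  for (shape in c("hann", "flat", "tukey")) {
    cfg <- simConfig(effects = list(
      covariateEffect("age", -0.3, c(7, 10), shape = shape)),
      weekendDayMultiplier = 1)
    base <- latentMeanCurve(cfg, age = 5.5, sex = "F", mass = 24.05)
    old <- latentMeanCurve(cfg, age = 9, sex = "F", mass = 24.05)
    minutes <- 0:1439
    inside <- minutes >= 420 & minutes < 600
    expect_identical(old[!inside], base[!inside])
    expect_true(all(old[inside][2:178] < base[inside][2:178]))
  }
})

test_that("effect curves wrap midnight and respect their taper shapes", {
  e <- covariateEffect("mass", 0.5, c(23, 1), shape = "flat")
  v <- effectCurveValue(e, 0:1439)
  expect_equal(sum(v > 0), 120)
  expect_equal(unname(v[1]), 0.5)          # 00:00 inside the wrapped window
  expect_equal(unname(v[12 * 60 + 1]), 0)  # noon outside

  h <- covariateEffect("age", 1, c(6, 8), shape = "hann")
  vh <- effectCurveValue(h, 0:1439)
  expect_equal(max(vh), 1, tolerance = 1e-6)
  expect_equal(which.max(vh) - 1L, 7L * 60L)  # peak at the window centre
  expect_equal(unname(vh[6 * 60 + 1]), 0)     # zero at the edge
})

test_that("gap masking is probabilistically and structurally correct", {
  co <- simulateCohort(tinyConfig(), seed = 4)
  s <- series(co, "dog01")
  expect_identical(applyGaps(s, 0), s)

  allGone <- applyGaps(s, 1, seed = 1, mode = "day")
  expect_true(all(isMissing(allGone)))
  # masked epochs carry an explicit marker, never zero
  expect_true(all(is.na(activityCounts(allGone))))
  expect_identical(allGone@counts, s@counts)   # raw values untouched

  long <- epochSeries("x", as.POSIXct("2020-01-06", tz = "UTC"),
                      rep(1L, 1000 * 1440), epochMinutes = 1)
  gapped <- applyGaps(long, 0.5, seed = 7, mode = "day")
  dayMissing <- colMeans(matrix(isMissing(gapped), 1440, 1000)) == 1
  # binomial 99% interval around 0.5 for 1000 days
  expect_gt(mean(dayMissing), 0.5 - 2.58 * sqrt(0.25 / 1000))
  expect_lt(mean(dayMissing), 0.5 + 2.58 * sqrt(0.25 / 1000))

  spanned <- applyGaps(s, 1, seed = 3, mode = "span")
  expect_true(any(isMissing(spanned)) && !all(isMissing(spanned)))
})
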