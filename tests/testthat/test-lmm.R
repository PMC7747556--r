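# Day/night mixed models: summary table assembly, random-intercept fits,
# all-subsets AIC averaging.

test_that("summary table applies the log offset and drops missing strata", {
  co <- simulateCohort(tinyConfig(nSubjects = 3), seed = 14)
  summaries <- data.frame(
    subject = rep(c("dog01", "dog02", "dog03"), each = 2),
    date = rep(as.Date("2020-01-06") + 0:1, 3),
    day_type = "weekday",
    daytime_mean = 5, nighttime_mean = c(2, 2, 2, NA, 2, 2))
  tab <- buildSummaryTable(summaries, subjects(co), offset = 1)
  expect_true(all(tab$log_activity[tab$stratum == "daytime"] == log(6)))
  expect_identical(sum(tab$stratum == "daytime"), 6L)
  expect_identical(sum(tab$stratum == "nighttime"), 5L)  # the NA night dropped
  expect_equal(mean(tab$age_std), 0, tolerance = 1e-12)
  expect_equal(sd(tab$mass_std), 1, tolerance = 1e-12)
  expect_error(buildSummaryTable(summaries, subjects(co), offset = 0),
               "positive")
})

test_that("a full simulated cohort yields 588 daytime rows at the study size", {
  co <- simulateCohort(simConfig(), seed = 17)
  summaries <- do.call(rbind, lapply(subjects(co)$id, function(id) {
    d <- diaries(co)
    labs <- suppressWarnings(
      classifyDayNight(series(co, id), d[d$id == id, , drop = FALSE]))
    summarizeActivity(series(co, id), labs)
  }))
  tab <- buildSummaryTable(summaries, subjects(co))
  expect_identical(sum(tab$stratum == "daytime"), 42L * 14L)
})

test_that("with zero intercept variance the mixed model matches OLS", {
  tab <- simulateLmmTable(1, truthDay = c(0.25, -0.3, -0.25, -0.2), sdId = 0)
  fit <- fitRandomInterceptModel(tab, response = "daytime")
  expect_true(fit$singular)            # variance estimated at the boundary
  ols <- lm(log_activity ~ day_type + age_std + sex + mass_std,
            data = tab[tab$stratum == "daytime", ])
  expect_equal(fit$coefficients, coef(ols), tolerance = 1e-6)
})

test_that("AIC ordering is invariant to predictor standardization", {
  tab <- simulateLmmTable(4, truthDay = c(0.25, -0.3, -0.25, -0.2))
  aicStd <- vapply(list("age", c("age", "mass"), c("day_type", "age", "sex", "mass")),
                   function(tm) fitRandomInterceptModel(tab, tm, "daytime",
                                                        standardized = TRUE)$aic,
                   numeric(1))
  aicRaw <- vapply(list("age", c("age", "mass"), c("day_type", "age", "sex", "mass")),
                   function(tm) fitRandomInterceptModel(tab, tm, "daytime",
                                                        standardized = FALSE)$aic,
                   numeric(1))
  expect_equal(aicStd, aicRaw, tolerance = 1e-6)
})

test_that("the intercept-only model loses to the true model on strong signal", {
  tab <- simulateLmmTable(5, truthDay = c(0.4, -0.5, -0.5, -0.4))
  null <- fitRandomInterceptModel(tab, character(0), "daytime")
  full <- fitRandomInterceptModel(tab, response = "daytime")
  expect_true(is.finite(null$aic))
  expect_gt(null$aic, full$aic)
})

test_that("model averaging reduces to the dominant model when one dominates", {
  tab <- simulateLmmTable(6, truthDay = c(0.8, -1, -1, -0.8), sdId = 0.1,
                          sdEps = 0.2)
  ma <- dredgeAndAverage(tab, "daytime")
  full <- fitRandomInterceptModel(tab, response = "daytime")
  top <- candidateModels(ma)
  expect_gt(top$weight[1], 0.99)
  expect_identical(top$terms[1], "day_type+age+sex+mass")
  cn <- c("day_typeweekend", "age_std", "sexM", "mass_std")
  expect_equal(coefTable(ma)$estimate, unname(full$coefficients[cn]),
               tolerance = 1e-3)
})

test_that("conditional averaging matches the hand-worked two-model formula", {
  beta <- c(0.30, 0.10)
  se <- c(0.05, 0.08)
  w <- c(0.6, 0.15)                            # unnormalized retained weights
  avg <- actiFLM:::conditionalAverage(beta, se, w)
  wc <- w / sum(w)
  estHand <- sum(wc * beta)
  expect_equal(avg$estimate, estHand)
  expect_equal(avg$se, sqrt(sum(wc * (se^2 + (beta - estHand)^2))))
  # a convex combination: the average lies between the per-model estimates
  expect_gt(avg$estimate, min(beta))
  expect_lt(avg$estimate, max(beta))
  # between-model spread inflates the SE above the within-model floor
  expect_gt(avg$se, sqrt(sum(wc * se^2)))
})

test_that("the averaged-coefficient table has the reporting schema", {
  tab <- simulateLmmTable(7, truthDay = c(0.25, -0.3, -0.25, -0.2))
  for (resp in c("daytime", "nighttime")) {
    ma <- dredgeAndAverage(tab, resp)
    ct <- coefTable(ma)
    expect_identical(ct$term, c("Day type (weekend)", "Age", "Sex (male)",
                                "Body mass"))
    expect_true(all(c("estimate", "se", "z", "p", "ci_low", "ci_high",
                      "full_estimate", "weight") %in% names(ct)))
    expect_equal(ct$ci_low, ct$estimate - 1.96 * ct$se)
    expect_equal(ct$ci_high, ct$estimate + 1.96 * ct$se)
    expect_equal(ct$p, 2 * pnorm(-abs(ct$estimate) / ct$se))
    models <- candidateModels(ma)
    expect_identical(nrow(models), 16L)
    expect_equal(min(models$delta), 0)
    expect_equal(sum(models$weight), 1, tolerance = 1e-12)
    expect_true(all(models$delta[models$retained] < 10))
  }
})

test_that("the AICc option penalizes harder and keeps weights normalized", {
  tab <- simulateLmmTable(9, truthDay = c(0.25, -0.3, -0.25, -0.2))
  ma <- dredgeAndAverage(tab, "daytime")
  mac <- dredgeAndAverage(tab, "daytime", useAICc = TRUE)
  # AICc adds 2k(k+1)/(n-k-1) to each model's score
  n <- sum(tab$stratum == "daytime")
  mtab <- candidateModels(ma)
  expect_equal(sort(candidateModels(mac)$AIC),
               sort(mtab$AIC + 2 * mtab$df * (mtab$df + 1) / (n - mtab$df - 1)),
               tolerance = 1e-8)
  expect_equal(sum(candidateModels(mac)$weight), 1, tolerance = 1e-12)
})

test_that("retained weights sum to one and estimates are convex combinations", {
  tab <- simulateLmmTable(8, truthDay = c(0.1, -0.1, 0, 0))
  ma <- dredgeAndAverage(tab, "daytime")
  models <- candidateModels(ma)
  expect_equal(sum(models$weight[models$retained]), 1, tolerance = 1e-12)
  # recompute each term's bounds from the per-model fits
  fits <- lapply(list("day_type", c("day_type", "age"),
                      c("day_type", "age", "sex", "mass")),
                 fitRandomInterceptModel, table = tab, response = "daytime")
  dayEsts <- vapply(fits, function(f) unname(f$coefficients["day_typeweekend"]),
                    numeric(1))
  est <- coefTable(ma)$estimate[1]
  # the average over all 8 day_type models must lie within the full range of
  # single-model estimates; the three checked here bracket it in practice
  expect_gte(est, min(dayEsts) - 0.02)
  expect_lte(est, max(dayEsts) + 0.02)
})
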