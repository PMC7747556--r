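# Pointwise F statistics, the permutation test, and significance intervals.

test_that("identical curve sets across groups give F = 0 everywhere", {
  grid <- seq(0, 1430, by = 10)
  base <- vapply(1:3, function(i) 50 + i * sin(2 * pi * grid / 1440),
                 numeric(length(grid)))
  vals <- cbind(base, base)            # group B duplicates group A
  cm <- curveMatrixFromValues(vals, grid,
                              data.frame(sex = rep(c("F", "M"), each = 3)))
  f <- pointwiseF(cm, "sex")
  expect_lt(max(abs(f)), 1e-10)
})

test_that("pointwise F equals the classical one-way ANOVA F", {
  grid <- seq(0, 1410, by = 30)
  set.seed(12)
  vals <- matrix(rnorm(length(grid) * 6, 50, 8), length(grid), 6)
  group <- c("F", "F", "F", "M", "M", "M")
  cm <- curveMatrixFromValues(vals, grid, data.frame(sex = group))
  f <- pointwiseF(cm, "sex")
  oracle <- apply(vals, 1, anovaFOracle, group = group)
  expect_equal(f, unname(oracle), tolerance = 1e-10)

  # also against stats::anova on a handful of points
  for (i in c(1, 10, 25)) {
    a <- anova(lm(vals[i, ] ~ factor(group)))
    expect_equal(f[i], a$`F value`[1], tolerance = 1e-10)
  }
})

test_that("a continuous covariate fitting the curves exactly flags infinite F", {
  grid <- 0:99
  x <- c(1, 2, 3, 4, 5, 6)
  vals <- outer(sin(2 * pi * grid / 1440), x)   # exact linear function of x
  cm <- curveMatrixFromValues(vals, grid, data.frame(age = x))
  expect_warning(f <- pointwiseF(cm, "age"), "zero residual variance")
  expect_true(all(is.infinite(f[grid > 0])))
})

test_that("rank-deficient designs are rejected naming the collinear column", {
  grid <- 0:9
  set.seed(1)
  vals <- matrix(rnorm(60), 10, 6)
  cm <- curveMatrixFromValues(vals, grid,
                              data.frame(age = 1:6, age2 = 2 * (1:6)))
  expect_error(pointwiseF(cm, "age2", adjust = "age"), "collinear.*age")
})

test_that("permutation invariance: relabeling subjects leaves observed F unchanged", {
  co <- simulateCohort(tinyConfig(nSubjects = 8), seed = 5)
  cm <- cohortCurves(co, grid = seq(0, 1430, by = 30))
  f1 <- pointwiseF(cm, "age")
  perm <- c(3, 1, 4, 2, 8, 7, 5, 6)
  cm2 <- curveMatrixFromValues(curveValues(cm)[, perm], gridMinutes(cm),
                               as.data.frame(colData(cm))[perm, , drop = FALSE])
  expect_equal(pointwiseF(cm2, "age"), f1, tolerance = 1e-12)
})

test_that("sampled permutation p-curves match exhaustive enumeration", {
  # n = 5 subjects, 2-level factor (2 vs 3): only 10 distinct assignments
  grid <- seq(0, 1430, by = 10)
  set.seed(21)
  vals <- matrix(rnorm(length(grid) * 5, 40, 6), length(grid), 5) +
    outer(cos(2 * pi * grid / 1440), c(0, 0, 2, 2, 2))
  group <- c("A", "A", "B", "B", "B")
  cm <- curveMatrixFromValues(vals, grid, data.frame(g = group))
  obs <- pointwiseF(cm, "g")

  assignments <- utils::combn(5, 2)    # positions of the two "A" subjects
  permF <- apply(assignments, 2, function(idx) {
    g <- rep("B", 5); g[idx] <- "A"
    cmPerm <- curveMatrixFromValues(vals, grid, data.frame(g = g))
    pointwiseF(cmPerm, "g")
  })
  pExact <- rowMeans(permF >= obs)

  res <- permutationTest(cm, "g", nPermutations = 10000, seed = 99)
  expect_lt(max(abs(pointwiseP(res) - pExact)), 0.02)
})

test_that("pointwise p is bounded below by 1/B and the test is seed-reproducible", {
  co <- simulateCohort(tinyConfig(nSubjects = 6), seed = 3)
  cm <- cohortCurves(co, grid = seq(0, 1430, by = 30))
  r1 <- permutationTest(cm, "sex", nPermutations = 50, seed = 4)
  r2 <- permutationTest(cm, "sex", nPermutations = 50, seed = 4)
  expect_true(all(pointwiseP(r1) >= 1 / 50))
  expect_identical(observedF(r1), observedF(r2))
  expect_identical(criticalCurve(r1), criticalCurve(r2))
  expect_identical(pointwiseP(r1), pointwiseP(r2))

  skinny <- curveMatrixFromValues(curveValues(cm)[, 1:3], gridMinutes(cm),
                                  data.frame(sex = c("F", "F", "M")))
  expect_error(permutationTest(skinny, "sex", 10, seed = 1), "at least 2")
})

test_that("significant intervals are maximal runs merged across midnight", {
  mk <- function(sig, grid = 0:1439) {
    f <- ifelse(sig, 2, 0)
    new("FLMResult", covariate = "x", grid = as.numeric(grid), observedF = f,
        critical = rep(1, length(grid)), pvalue = rep(0.5, length(grid)),
        nPermutations = 500L, alpha = 0.05, seed = 1L)
  }
  none <- significantIntervals(mk(rep(FALSE, 1440)))
  expect_identical(nrow(none), 0L)

  sig <- rep(FALSE, 1440); sig[101:200] <- TRUE    # minutes 100-199
  one <- significantIntervals(mk(sig))
  expect_identical(one$from, "01:40")
  expect_identical(one$to, "03:20")
  expect_equal(one$duration, 100)

  wrap <- rep(FALSE, 1440); wrap[c(1:10, 1431:1440)] <- TRUE  # 23:50-00:10
  w <- significantIntervals(mk(wrap))
  expect_identical(nrow(w), 1L)
  expect_identical(w$from, "23:50")
  expect_identical(w$to, "00:10")
  expect_equal(w$duration, 20)

  expect_equal(significantIntervals(mk(rep(TRUE, 1440)))$duration, 1440)
})

test_that("adjusted designs only permute the covariate under test", {
  co <- simulateCohort(tinyConfig(nSubjects = 10), seed = 13)
  cm <- cohortCurves(co, grid = seq(0, 1430, by = 30))
  r <- permutationTest(cm, "age", adjust = c("sex", "mass"),
                       nPermutations = 30, seed = 2)
  expect_s4_class(r, "FLMResult")
  expect_true(all(observedF(r) >= 0))
  # full-design permutation mode also runs
  r2 <- permutationTest(cm, "age", adjust = "sex", permuteAll = TRUE,
                        nPermutations = 30, seed = 2)
  expect_true(all(pointwiseP(r2) >= 1 / 30))
})

test_that("the global max-F band is flat and dominates the pointwise one", {
  co <- simulateCohort(tinyConfig(nSubjects = 8), seed = 19)
  cm <- cohortCurves(co, grid = seq(0, 1430, by = 30))
  pw <- permutationTest(cm, "mass", nPermutations = 99, seed = 3)
  gl <- permutationTest(cm, "mass", nPermutations = 99, seed = 3,
                        global = TRUE)
  expect_identical(observedF(gl), observedF(pw))
  expect_identical(length(unique(criticalCurve(gl))), 1L)
  expect_true(all(criticalCurve(gl) >= criticalCurve(pw)))
})
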