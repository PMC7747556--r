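# Pointwise functional linear model: an F statistic at every clock minute,
# with a permutation-derived pointwise critical-value curve.

#' @include AllGenerics.R AllClasses.R
NULL

#' Build a regression design from CurveMatrix covariates
#'
#' Expands the covariate under test (and any adjustment covariates) from
#' `colData` into a full-rank design matrix with intercept; factors get
#' treatment contrasts. Returns the matrix plus the indices of the columns
#' belonging to the tested covariate.
#'
#' @param curves a [CurveMatrix].
#' @param covariate name of the `colData` column under test.
#' @param adjust character vector of additional `colData` columns kept in
#'   both the full and the reduced model.
#' @return list with elements `design` (n x p matrix) and `testColumns`.
#' @export
flmDesign <- function(curves, covariate, adjust = character()) {
  cd <- as.data.frame(colData(curves))
  for (v in c(covariate, adjust)) {
    if (!v %in% names(cd)) stop("no covariate '", v, "' in colData",
                                call. = FALSE)
  }
  expand <- function(v) {
    x <- cd[[v]]
    if (is.character(x) || is.factor(x) || is.logical(x)) {
      x <- factor(x)
      m <- stats::model.matrix(~x)[, -1L, drop = FALSE]
      colnames(m) <- paste0(v, levels(x)[-1L])
      m
    } else {
      matrix(as.numeric(x), ncol = 1L, dimnames = list(NULL, v))
    }
  }
  blocks <- lapply(c(adjust, covariate), expand)
  X <- cbind(`(Intercept)` = 1, do.call(cbind, blocks))
  q <- ncol(blocks[[length(blocks)]])
  list(design = X, testColumns = seq.int(ncol(X) - q + 1L, ncol(X)))
}

# Residual sums of squares of OLS of each row of Y' on X, via QR.
# Y: grid x n matrix; X: n x p. Returns per-grid-point SSE.
sseByPoint <- function(Y, X) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[seq.int(qrX$rank + 1L, ncol(X))]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  res <- qr.resid(qrX, t(Y))
  colSums(res^2)
}

#' Pointwise F statistics across the day
#'
#' At each grid minute, ordinary least squares of the subjects' smoothed
#' activity values on the design, comparing the full model against the
#' reduced model without the tested column(s):
#' \deqn{F(t) = \frac{(SSE_0(t) - SSE_1(t)) / q}{SSE_1(t) / (n - p)}.}
#' For a single two-level factor with intercept this is the classical
#' one-way ANOVA F. Grid points with zero full-model residual variance are
#' reported as `Inf` with a warning.
#'
#' @param curves a [CurveMatrix], or a plain grid-by-subjects matrix.
#' @param covariate tested `colData` column (CurveMatrix input), or a list
#'   as returned by [flmDesign()] when `curves` is a plain matrix.
#' @param adjust additional covariates kept in both models.
#' @return numeric vector of F statistics, one per grid point.
#' @export
pointwiseF <- function(curves, covariate, adjust = character()) {
  if (is(curves, "CurveMatrix")) {
    d <- flmDesign(curves, covariate, adjust)
    Y <- curveValues(curves)
  } else {
    stopifnot(is.list(covariate), !is.null(covariate$design))
    d <- covariate
    Y <- curves
  }
  pointwiseFStat(Y, d$design, d$testColumns)
}

pointwiseFStat <- function(Y, X, testColumns) {
  n <- ncol(Y)
  stopifnot(nrow(X) == n)
  p <- ncol(X)
  if (n <= p) stop("need more subjects (", n, ") than design columns (", p,
                   ")", call. = FALSE)
  q <- length(testColumns)
  sseFull <- sseByPoint(Y, X)
  sseRed <- sseByPoint(Y, X[, -testColumns, drop = FALSE])
  Fstat <- pmax(0, (sseRed - sseFull) / q) / (sseFull / (n - p))
  # degenerate points, judged against the total variation across subjects:
  # no variation at all -> F = 0; real variation fitted exactly -> F = Inf
  s0 <- rowSums((Y - rowMeans(Y))^2)
  constant <- s0 <= .Machine$double.eps^2 * pmax(rowSums(Y^2), 1)
  perfect <- !constant & sseFull <= 1e-10 * s0
  Fstat[constant] <- 0
  if (any(perfect)) {
    Fstat[perfect] <- Inf
    warning("zero residual variance at ", sum(perfect),
            " grid point(s); F reported as Inf", call. = FALSE)
  }
  Fstat[is.nan(Fstat)] <- 0
  Fstat
}

#' Pointwise permutation F-test for a covariate effect across the day
#'
#' Computes the observed F curve, then re-computes it under
#' `nPermutations` re-assignments of the tested covariate values to
#' subjects (whole curves stay fixed; the subject is the exchangeable unit
#' under the null of no covariate effect). The observed assignment is
#' always included as the first permutation, so pointwise p-values are
#' bounded below by `1/nPermutations` and the test is exactly calibrated.
#' The critical curve at each grid minute is the empirical \eqn{(1-\alpha)}
#' order-statistic quantile of the permutation F values, and the pointwise
#' p-curve is the proportion of permutation F values at least as large as
#' the observed one.
#'
#' When adjustment covariates are present only the tested column(s) are
#' permuted against the rest (simple permutation of the covariate under
#' test); set `permuteAll = TRUE` to permute the full design instead.
#'
#' @param curves a [CurveMatrix].
#' @param covariate tested `colData` column.
#' @param nPermutations number of permutations (default 500).
#' @param alpha pointwise significance level (default 0.05).
#' @param seed integer seed for the permutation stream.
#' @param adjust covariates retained in both full and reduced models.
#' @param permuteAll permute rows of all non-intercept columns together.
#' @param global use a global (max-F) band: the critical curve becomes the
#'   flat empirical \eqn{(1-\alpha)} quantile of each permutation's maximum
#'   F over the grid, controlling the family-wise error across minutes.
#'   The default is the pointwise test.
#' @return an [FLMResult].
#' @examples
#' cohort <- simulateCohort(simConfig(nSubjects = 12, nDays = 2), seed = 1)
#' curves <- evaluateCurves(
#'   lapply(series(cohort), function(s) fourierFit(averageDailyProfile(s))),
#'   grid = seq(0, 1430, by = 10), colData = subjects(cohort))
#' res <- permutationTest(curves, "sex", nPermutations = 99, seed = 1)
#' res
#' @export
permutationTest <- function(curves, covariate, nPermutations = 500L,
                            alpha = 0.05, seed = 1L, adjust = character(),
                            permuteAll = FALSE, global = FALSE) {
  stopifnot(is(curves, "CurveMatrix"), nPermutations >= 1L,
            alpha > 0, alpha < 1)
  cd <- as.data.frame(colData(curves))
  x <- cd[[covariate]]
  if (is.character(x) || is.factor(x)) {
    if (any(table(x) < 2L)) {
      stop("each level of '", covariate, "' needs at least 2 subjects",
           call. = FALSE)
    }
  }
  d <- flmDesign(curves, covariate, adjust)
  Y <- curveValues(curves)
  n <- ncol(Y)
  obsF <- suppressWarnings(pointwiseFStat(Y, d$design, d$testColumns))

  permCols <- if (permuteAll) seq.int(2L, ncol(d$design)) else d$testColumns
  nPermutations <- as.integer(nPermutations)
  permF <- withSeed(seed, {
    vapply(seq_len(nPermutations), function(b) {
      if (b == 1L) return(obsF)          # observed assignment always included
      Xb <- d$design
      Xb[, permCols] <- Xb[sample.int(n), permCols, drop = FALSE]
      suppressWarnings(pointwiseFStat(Y, Xb, d$testColumns))
    }, numeric(nrow(Y)))
  })
  # empirical order-statistic quantile, per grid point or of the max-F
  k <- min(nPermutations, ceiling((1 - alpha) * nPermutations))
  crit <- if (global) {
    maxF <- apply(permF, 2L, max)
    rep(sort(maxF)[k], nrow(Y))
  } else {
    apply(permF, 1L, function(v) sort(v)[k])
  }
  pcurve <- rowMeans(permF >= obsF)

  new("FLMResult", covariate = covariate, grid = gridMinutes(curves),
      observedF = obsF, critical = crit, pvalue = pcurve,
      nPermutations = nPermutations, alpha = alpha,
      seed = as.integer(seed))
}

#' Clock-time intervals where the covariate effect is significant
#'
#' Maximal runs of consecutive grid minutes where the observed F strictly
#' exceeds the permutation critical curve, merged across midnight (a run
#' spanning 23:50 to 00:10 is one interval). Intervals are half-open
#' `[from, to)` in clock time; `duration` assumes a uniform grid.
#'
#' @param x an [FLMResult].
#' @param ... unused.
#' @return data.frame with columns `from`, `to` ("HH:MM"), `start_minute`,
#'   `end_minute`, `duration` (minutes); zero rows when nothing is
#'   significant.
#' @export
setMethod("significantIntervals", "FLMResult", function(x, ...) {
  sig <- x@observedF > x@critical
  grid <- x@grid
  G <- length(grid)
  empty <- data.frame(from = character(), to = character(),
                      start_minute = numeric(), end_minute = numeric(),
                      duration = numeric())
  if (!any(sig)) return(empty)
  spacing <- if (G > 1L) min(diff(grid)) else MINUTES_PER_DAY
  if (all(sig)) {
    return(data.frame(from = minutesToClock(grid[1L]),
                      to = minutesToClock(grid[1L]),
                      start_minute = grid[1L], end_minute = grid[1L],
                      duration = G * spacing))
  }
  r <- rle(sig)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  if (sig[1L] && sig[G]) {           # merge the midnight wrap
    runs$start[1L] <- runs$start[nrow(runs)]
    runs <- runs[-nrow(runs), , drop = FALSE]
  }
  out <- data.frame(
    from = minutesToClock(grid[runs$start]),
    to = minutesToClock((grid[runs$end] + spacing) %% MINUTES_PER_DAY),
    start_minute = grid[runs$start],
    end_minute = (grid[runs$end] + spacing) %% MINUTES_PER_DAY,
    duration = ((grid[runs$end] + spacing - grid[runs$start]) %%
                  MINUTES_PER_DAY))
  out$duration[out$duration == 0] <- MINUTES_PER_DAY
  rownames(out) <- NULL
  out
})

#' Fraction of grid minutes declared significant
#'
#' @param x an [FLMResult].
#' @return proportion of grid points where observed F exceeds the critical
#'   curve.
#' @export
significantFraction <- function(x) {
  stopifnot(is(x, "FLMResult"))
  mean(x@observedF > x@critical)
}
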