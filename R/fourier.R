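# Functional representation: per-minute across-day averaging and truncated
# Fourier-basis least squares.

#' @include AllGenerics.R AllClasses.R
NULL

#' Average a multi-day record into a 24-h diurnal profile
#'
#' For each of the 1440 clock minutes, the mean of non-missing counts at
#' that minute across all recorded days (epochs coarser than 1 minute
#' contribute to the clock minute they start on).
#'
#' @param series an [EpochSeries].
#' @return a [DiurnalProfile].
#' @export
averageDailyProfile <- function(series) {
  if (all(isMissing(series))) {
    stop("all epochs missing for subject ", subjectId(series), call. = FALSE)
  }
  minute <- as.integer(epochClock(series)$minute)
  ok <- !isMissing(series)
  sums <- rep(0, MINUTES_PER_DAY)
  n <- rep(0L, MINUTES_PER_DAY)
  idx <- minute[ok] + 1L
  agg <- rowsum(series@counts[ok], idx)
  cnt <- rowsum(rep(1L, sum(ok)), idx)
  at <- as.integer(rownames(agg))
  sums[at] <- agg[, 1L]
  n[at] <- cnt[, 1L]
  means <- ifelse(n > 0L, sums / pmax(n, 1L), NA_real_)
  new("DiurnalProfile", subjectId = subjectId(series), meanCounts = means,
      nDays = n)
}

#' Fourier basis matrix for the 24-h period
#'
#' Columns `{1, cos(2*pi*k*t/1440), sin(2*pi*k*t/1440)}` for `k = 1..K`,
#' evaluated at `minutes`.
#' @noRd
fourierBasis <- function(minutes, nHarmonics) {
  ang <- outer(2 * pi * minutes / MINUTES_PER_DAY, seq_len(nHarmonics))
  cbind(1, cos(ang), sin(ang))
}

#' Fit a truncated Fourier series to a diurnal profile
#'
#' Least-squares projection of the per-minute profile onto the periodic
#' basis `{1, cos(2*pi*k*t/24h), sin(2*pi*k*t/24h)}, k = 1..K`, fitted on
#' non-missing minutes only (the basis interpolates through gaps). No
#' roughness penalty is applied.
#'
#' @param profile a [DiurnalProfile].
#' @param nHarmonics number of harmonics K (default 9, i.e. 19
#'   coefficients).
#' @return a [FourierCurve] (residual sum of squares in `@rss`).
#' @examples
#' cohort <- simulateCohort(simConfig(nSubjects = 2, nDays = 3), seed = 1)
#' curve <- fourierFit(averageDailyProfile(series(cohort, "dog01")))
#' curve
#' @export
fourierFit <- function(profile, nHarmonics = 9L) {
  stopifnot(is(profile, "DiurnalProfile"))
  nHarmonics <- as.integer(nHarmonics)
  if (nHarmonics < 1L) stop("nHarmonics must be >= 1", call. = FALSE)
  ok <- profile@nDays > 0L
  p <- 2L * nHarmonics + 1L
  if (sum(ok) < p) {
    stop("profile has ", sum(ok), " observed minutes but the basis needs ",
         p, call. = FALSE)
  }
  minutes <- which(ok) - 1L
  X <- fourierBasis(minutes, nHarmonics)
  fit <- lm.fit(X, profile@meanCounts[ok])
  beta <- unname(fit$coefficients)
  new("FourierCurve", subjectId = profile@subjectId,
      intercept = beta[1L],
      cosCoefs = unname(beta[2L:(nHarmonics + 1L)]),
      sinCoefs = unname(beta[(nHarmonics + 2L):p]),
      rss = sum(fit$residuals^2), nObs = sum(ok))
}

#' Evaluate a cohort's smoothed curves on a common grid
#'
#' Builds the [CurveMatrix] that feeds the functional linear model: grid
#' minutes as rows, subjects as columns, the `"activity"` assay holding
#' raw curve evaluations (negative dips from the truncated basis are kept
#' for inference; floor them at zero only for display).
#'
#' @param curves named list of [FourierCurve] objects, in cohort order.
#' @param grid evaluation grid in minutes since midnight (default every
#'   minute of the day).
#' @param colData data.frame of per-subject covariates, rows aligned with
#'   and named after `curves` (e.g. `subjects(cohort)`).
#' @return a [CurveMatrix].
#' @export
evaluateCurves <- function(curves, grid = seq_len(MINUTES_PER_DAY) - 1L,
                           colData = NULL) {
  vals <- vapply(curves, evaluateCurve, numeric(length(grid)),
                 minutes = grid)
  vals <- matrix(vals, nrow = length(grid),
                 dimnames = list(NULL, vapply(curves, subjectId, character(1))))
  if (is.null(colData)) {
    colData <- DataFrame(row.names = colnames(vals))
  } else {
    stopifnot(nrow(colData) == ncol(vals))
    colData <- DataFrame(colData, row.names = colnames(vals))
  }
  se <- SummarizedExperiment(
    assays = list(activity = vals),
    rowData = DataFrame(minute = as.numeric(grid)),
    colData = colData)
  new("CurveMatrix", se)
}

setMethod("subjectId", "FourierCurve", function(x) x@subjectId)

#' Grid minutes of a CurveMatrix
#' @param x a [CurveMatrix].
#' @rdname CurveMatrix-class
#' @export
gridMinutes <- function(x) as.numeric(rowData(x)$minute)

#' @rdname CurveMatrix-class
#' @export
curveValues <- function(x) assay(x, "activity")
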