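# Display helpers: per-subject spaghetti of smoothed curves with the
# cohort mean, and the two-panel covariate-effect display (group mean
# curves over F-vs-critical).

#' Plot smoothed activity curves for a cohort
#'
#' Per-subject smoothed 24-h curves (floored at zero for display) with the
#' cohort mean overlaid.
#'
#' @param curves a [CurveMatrix].
#' @param main plot title.
#' @return invisibly, the cohort mean curve.
#' @export
plotCurves <- function(curves, main = "Smoothed 24-h activity") {
  vals <- pmax(curveValues(curves), 0)
  grid <- gridMinutes(curves) / 60
  matplot(grid, vals, type = "l", lty = 1,
          col = adjustcolor("grey40", alpha.f = 0.35),
          xlab = "clock hour", ylab = "activity (counts/min)", main = main,
          xaxt = "n")
  axis(1, at = seq(0, 24, by = 4))
  m <- rowMeans(vals)
  lines(grid, m, lwd = 3, col = "firebrick")
  invisible(m)
}

#' Two-panel covariate-effect display
#'
#' Upper panel: mean smoothed curves by covariate group (median split for
#' continuous covariates). Lower panel: observed F (solid) against the
#' pointwise permutation critical curve (dotted); minutes where the solid
#' line is above the dotted one differ significantly, and are shaded.
#'
#' @param curves the [CurveMatrix] tested.
#' @param result the corresponding [FLMResult].
#' @return invisibly, the significant intervals.
#' @export
plotFLM <- function(curves, result) {
  cd <- as.data.frame(colData(curves))
  x <- cd[[result@covariate]]
  groups <- if (is.numeric(x)) {
    factor(ifelse(x <= stats::median(x), "low", "high"),
           levels = c("low", "high"))
  } else factor(x)
  grid <- gridMinutes(curves) / 60
  vals <- pmax(curveValues(curves), 0)

  op <- par(mfrow = c(2, 1), mar = c(2.5, 4, 2, 1))
  on.exit(par(op), add = TRUE)
  gm <- vapply(levels(groups), function(g)
    rowMeans(vals[, groups == g, drop = FALSE]), numeric(nrow(vals)))
  matplot(grid, gm, type = "l", lty = 1, lwd = 2, col = c("steelblue", "tomato"),
          xlab = "", ylab = "activity (counts/min)",
          main = paste("Effect of", result@covariate), xaxt = "n")
  axis(1, at = seq(0, 24, by = 4))
  legend("topright", legend = levels(groups), lwd = 2, bty = "n",
         col = c("steelblue", "tomato"))

  iv <- significantIntervals(result)
  finF <- result@observedF[is.finite(result@observedF)]
  ylim <- range(0, finF, result@critical)
  plot(grid, pmin(result@observedF, max(ylim)), type = "l", col = "red",
       lwd = 2, ylim = ylim, xlab = "clock hour", ylab = "F statistic",
       xaxt = "n")
  axis(1, at = seq(0, 24, by = 4))
  if (nrow(iv)) {
    for (i in seq_len(nrow(iv))) {
      x0 <- iv$start_minute[i] / 60
      x1 <- iv$end_minute[i] / 60
      if (x1 <= x0) {                     # wraps midnight
        rect(x0, ylim[1], 24, ylim[2], col = adjustcolor("gold", 0.3), border = NA)
        rect(0, ylim[1], x1, ylim[2], col = adjustcolor("gold", 0.3), border = NA)
      } else {
        rect(x0, ylim[1], x1, ylim[2], col = adjustcolor("gold", 0.3), border = NA)
      }
    }
    lines(grid, pmin(result@observedF, max(ylim)), col = "red", lwd = 2)
  }
  lines(grid, result@critical, col = "blue", lty = 3, lwd = 2)
  mtext(sprintf("pointwise test, %d permutations, alpha = %.2f",
                result@nPermutations, result@alpha), cex = 0.8)
  invisible(iv)
}
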