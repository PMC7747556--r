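# End-to-end orchestration: simulate/ingest -> validate -> smooth -> flm
# -> lmm -> report. All stage outputs are plain-text artifacts; all
# randomness flows from one root seed, split per stage deterministically.

#' Pipeline run configuration
#'
#' Plain list of every pipeline setting with the defaults used throughout:
#' 1-min epochs, 9 Fourier harmonics, 500 permutations at pointwise level
#' 0.05, delta-AIC retention threshold 10, log offset 1 count.
#'
#' @param cohortDir directory with an existing cohort (`NULL` to simulate).
#' @param outDir output directory for all artifacts.
#' @param simConfig a [SimConfig] used when `cohortDir` is `NULL`.
#' @param epochMinutes,nHarmonics,nPermutations,alpha,deltaMax,logOffset
#'   stage settings (see module functions).
#' @param covariates covariates tested in the functional linear model.
#' @param gridStep evaluation-grid spacing in minutes.
#' @param seed root seed; per-stage seeds are derived from it.
#' @return a `runConfig` list.
#' @export
runConfig <- function(cohortDir = NULL, outDir = tempfile("actiflm_run_"),
                      simConfig = actiFLM::simConfig(), epochMinutes = 1,
                      nHarmonics = 9, nPermutations = 500, alpha = 0.05,
                      deltaMax = 10, logOffset = 1,
                      covariates = c("age", "mass", "sex"), gridStep = 1,
                      seed = 1L) {
  stopifnot(epochMinutes > 0, nHarmonics > 0, nPermutations > 0,
            alpha > 0, alpha < 1, deltaMax > 0, logOffset > 0, gridStep > 0)
  structure(list(cohortDir = cohortDir, outDir = outDir,
                 simConfig = simConfig, epochMinutes = epochMinutes,
                 nHarmonics = nHarmonics, nPermutations = nPermutations,
                 alpha = alpha, deltaMax = deltaMax, logOffset = logOffset,
                 covariates = covariates, gridStep = gridStep,
                 seed = as.integer(seed)),
            class = "runConfig")
}

# Deterministic per-stage seeds derived from the root seed (kept < 2^31).
stageSeed <- function(seed, stage) {
  (as.integer(seed) * 131L + match(stage, c("simulate", "flm")) * 7919L) %%
    2147483647L
}

#' Run the full analysis pipeline
#'
#' Simulates (or ingests) a cohort, writes a QC report, smooths every
#' subject into a Fourier curve, runs the pointwise permutation F-test for
#' each requested covariate, fits the day/night mixed models with
#' all-subsets model averaging, and writes a markdown report plus figure
#' PNGs and TSV artifacts under `config$outDir`. Identical configs and
#' seeds give identical numeric outputs.
#'
#' @param config a [runConfig()] list.
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the cohort, curves, FLM results, model
#'   averages, the stage log and output paths.
#' @export
runPipeline <- function(config = runConfig(), quiet = FALSE) {
  stopifnot(inherits(config, "runConfig"))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  log <- list()
  say <- function(...) if (!quiet) message(...)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    log[[name]] <<- data.frame(stage = name,
                               seconds = round(proc.time()[["elapsed"]] - t0, 2))
    say(sprintf("[%s] done in %.1fs", name, log[[name]]$seconds))
    out
  }

  cohort <- stage("simulate", {
    if (is.null(config$cohortDir)) {
      co <- simulateCohort(config$simConfig, seed = stageSeed(config$seed, "simulate"))
      writeCohort(co, file.path(config$outDir, "cohort"))
      co
    } else readCohort(config$cohortDir, config$epochMinutes)
  })

  qc <- stage("validate", {
    q <- validateCohort(cohort)
    write.csv(q, file.path(config$outDir, "qc_report.csv"), row.names = FALSE)
    q
  })

  grid <- seq(0, MINUTES_PER_DAY - config$gridStep, by = config$gridStep)
  curves <- stage("smooth", {
    profiles <- lapply(series(cohort), averageDailyProfile)
    fcurves <- lapply(profiles, fourierFit, nHarmonics = config$nHarmonics)
    cm <- evaluateCurves(fcurves, grid = grid, colData = subjects(cohort))
    coefTab <- do.call(rbind, lapply(fcurves, function(fc) {
      data.frame(subject = subjectId(fc), coef = c("intercept",
                 paste0("cos", seq_along(fc@cosCoefs)),
                 paste0("sin", seq_along(fc@sinCoefs))),
                 value = c(fc@intercept, fc@cosCoefs, fc@sinCoefs))
    }))
    write.table(coefTab, file.path(config$outDir, "fourier_coefficients.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    write.table(cbind(minute = grid, curveValues(cm)),
                file.path(config$outDir, "curves.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    png(file.path(config$outDir, "fig_curves.png"), 900, 600)
    plotCurves(cm)
    dev.off()
    cm
  })

  flmResults <- stage("flm", {
    res <- list()
    for (cv in config$covariates) {
      r <- permutationTest(curves, cv, nPermutations = config$nPermutations,
                           alpha = config$alpha,
                           seed = stageSeed(config$seed, "flm"))
      write.table(data.frame(minute = r@grid, observed_F = r@observedF,
                             critical = r@critical, p = r@pvalue),
                  file.path(config$outDir, paste0("flm_", cv, ".tsv")),
                  sep = "\t", row.names = FALSE, quote = FALSE)
      iv <- significantIntervals(r)
      write.table(iv, file.path(config$outDir, paste0("flm_", cv, "_intervals.tsv")),
                  sep = "\t", row.names = FALSE, quote = FALSE)
      png(file.path(config$outDir, paste0("fig_flm_", cv, ".png")), 900, 700)
      plotFLM(curves, r)
      dev.off()
      res[[cv]] <- r
    }
    res
  })

  lmmResults <- stage("lmm", {
    summaries <- do.call(rbind, lapply(subjects(cohort)$id, function(id) {
      d <- diaries(cohort)
      labs <- classifyDayNight(series(cohort, id), d[d$id == id, , drop = FALSE])
      summarizeActivity(series(cohort, id), labs)
    }))
    tab <- buildSummaryTable(summaries, subjects(cohort),
                             offset = config$logOffset)
    write.table(tab, file.path(config$outDir, "summary_table.tsv"),
                sep = "\t", row.names = FALSE, quote = FALSE)
    out <- list()
    for (resp in c("daytime", "nighttime")) {
      ma <- dredgeAndAverage(tab, response = resp, deltaMax = config$deltaMax)
      write.table(coefTable(ma),
                  file.path(config$outDir, paste0("lmm_", resp, "_coefficients.tsv")),
                  sep = "\t", row.names = FALSE, quote = FALSE)
      write.table(candidateModels(ma),
                  file.path(config$outDir, paste0("lmm_", resp, "_models.tsv")),
                  sep = "\t", row.names = FALSE, quote = FALSE)
      out[[resp]] <- ma
    }
    out
  })

  logDf <- do.call(rbind, log)
  write.csv(logDf, file.path(config$outDir, "run_log.csv"), row.names = FALSE)
  reportPath <- writeReport(config, cohort, qc, flmResults, lmmResults)
  say("report: ", reportPath)
  invisible(list(cohort = cohort, curves = curves, flm = flmResults,
                 lmm = lmmResults, log = logDf, outDir = config$outDir,
                 report = reportPath))
}

# Markdown run report with the headline settings, per-covariate significant
# intervals and the two coefficient tables.
writeReport <- function(config, cohort, qc, flmResults, lmmResults) {
  path <- file.path(config$outDir, "report.md")
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# Actigraphy analysis report")
  w("")
  w("settings: %d permutations, alpha = %g, deltaAIC < %g, %g-min epochs, %d harmonics, seed %d",
    config$nPermutations, config$alpha, config$deltaMax, config$epochMinutes,
    config$nHarmonics, config$seed)
  w("")
  w("## Cohort")
  w("")
  w("%d subjects (%d F / %d M); median recording %.1f days; median missingness %.1f%%",
    nrow(qc), sum(qc$sex == "F"), sum(qc$sex == "M"),
    stats::median(qc$days), stats::median(qc$pct_missing))
  w("")
  w("![curves](fig_curves.png)")
  w("")
  w("## Functional linear models")
  for (cv in names(flmResults)) {
    r <- flmResults[[cv]]
    iv <- significantIntervals(r)
    w("")
    w("### %s", cv)
    w("")
    w("significant minutes: %.1f%% of the grid", 100 * significantFraction(r))
    if (nrow(iv)) {
      for (i in seq_len(nrow(iv))) {
        w("- %s to %s (%d min)", iv$from[i], iv$to[i], iv$duration[i])
      }
    }
    w("")
    w("![flm %s](fig_flm_%s.png)", cv, cv)
  }
  w("")
  w("## Day/night mixed models (conditional model averages)")
  for (resp in names(lmmResults)) {
    tab <- coefTable(lmmResults[[resp]])
    w("")
    w("### %s model", resp)
    w("")
    w("| Predictor | Estimate (SE) | z value | p value | 95%% CI |")
    w("|---|---|---|---|---|")
    for (i in seq_len(nrow(tab))) {
      w("| %s | %.3f (%.3f) | %.3f | %s | %.3f, %.3f |", tab$term[i],
        tab$estimate[i], tab$se[i], tab$z[i],
        if (tab$p[i] < 0.001) "< 0.001" else sprintf("%.3f", tab$p[i]),
        tab$ci_low[i], tab$ci_high[i])
    }
  }
  path
}
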