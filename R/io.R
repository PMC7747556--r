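# Reading, writing and validating epoch CSVs, cohort metadata and diaries.
#
# Epoch CSV dialect: header `timestamp,count[,missing]`, ISO-8601
# timestamps, integer counts, optional logical/0-1 missing flag. Exports
# from monitor software sometimes insert a units row under the header;
# it is detected and skipped.

#' Read one subject's epoch CSV
#'
#' Parses timestamps, validates that they are strictly increasing on a
#' fixed grid, and fills any holes in the grid with missing-marked epochs
#' (a gap is absence of data, never zero activity).
#'
#' @param path CSV file path.
#' @param epochMinutes expected epoch spacing in minutes; inferred from the
#'   first timestamp gap when `NULL`.
#' @param subjectId identifier for the series; defaults to the file name
#'   without extension.
#' @return an [EpochSeries].
#' @export
readEpochCSV <- function(path, epochMinutes = NULL, subjectId = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop("empty epoch file: ", path, call. = FALSE)
  names(raw) <- tolower(names(raw))
  if (!all(c("timestamp", "count") %in% names(raw))) {
    stop("epoch CSV needs 'timestamp' and 'count' columns: ", path,
         call. = FALSE)
  }
  # units row under the header (e.g. ",counts,") -> non-numeric first count
  if (is.na(suppressWarnings(as.numeric(raw$count[1L])))) {
    raw <- raw[-1L, , drop = FALSE]
    if (nrow(raw) == 0L) stop("empty epoch file: ", path, call. = FALSE)
  }
  ts <- as.POSIXct(sub("T", " ", raw$timestamp), tz = "UTC")
  if (anyNA(ts)) stop("unparsable timestamps in ", path, call. = FALSE)
  if (anyDuplicated(ts)) {
    stop("duplicated timestamp ",
         format(ts[anyDuplicated(ts)], "%Y-%m-%dT%H:%M:%S"),
         " in ", path, call. = FALSE)
  }
  if (is.unsorted(ts, strictly = TRUE)) {
    stop("non-monotone timestamps in ", path, call. = FALSE)
  }
  counts <- as.numeric(raw$count)
  miss <- if ("missing" %in% names(raw)) {
    as.logical(raw$missing) %in% TRUE
  } else rep(FALSE, nrow(raw))
  miss <- miss | is.na(counts)
  counts[is.na(counts)] <- 0

  if (is.null(epochMinutes)) {
    if (length(ts) < 2L) stop("cannot infer epoch spacing from one row",
                              call. = FALSE)
    epochMinutes <- min(as.numeric(difftime(ts[-1L], ts[-length(ts)],
                                            units = "mins")))
  }
  step <- epochMinutes * 60
  offsets <- as.numeric(difftime(ts, ts[1L], units = "secs")) / step
  if (any(abs(offsets - round(offsets)) > 1e-6)) {
    stop("timestamps do not sit on a ", epochMinutes,
         "-minute grid in ", path, call. = FALSE)
  }
  offsets <- as.integer(round(offsets))
  nTotal <- offsets[length(offsets)] + 1L
  full <- rep(0, nTotal)
  fullMiss <- rep(TRUE, nTotal)
  full[offsets + 1L] <- counts
  fullMiss[offsets + 1L] <- miss
  if (is.null(subjectId)) subjectId <- sub("\\.[^.]*$", "", basename(path))
  epochSeries(subjectId, ts[1L], full, epochMinutes, fullMiss)
}

#' Write one subject's epoch CSV
#'
#' Inverse of [readEpochCSV()]: `readEpochCSV(writeEpochCSV(s))` recovers
#' `s` for any series whose first and last epochs are observed.
#'
#' @param series an [EpochSeries].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeEpochCSV <- function(series, path) {
  df <- data.frame(
    timestamp = format(epochTimes(series), "%Y-%m-%dT%H:%M:%S", tz = "UTC"),
    count = as.integer(series@counts),
    missing = ifelse(series@missing, "TRUE", "FALSE"))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a cohort to a directory
#'
#' Writes one epoch CSV per subject (`epochs_<id>.csv`), the cohort
#' metadata (`metadata.csv`), the bedtime diary (`diary.csv`) and -- for
#' simulated cohorts -- the latent truth table (`truth.csv`).
#'
#' @param cohort an [ActivityCohort].
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(subjects(cohort), file.path(dir, "metadata.csv"),
            row.names = FALSE, quote = FALSE)
  if (nrow(diaries(cohort))) {
    write.csv(diaries(cohort), file.path(dir, "diary.csv"),
              row.names = FALSE, quote = FALSE)
  }
  if (nrow(cohortTruth(cohort))) {
    write.csv(cohortTruth(cohort), file.path(dir, "truth.csv"),
              row.names = FALSE, quote = FALSE)
  }
  for (id in names(series(cohort))) {
    writeEpochCSV(series(cohort, id), file.path(dir, paste0("epochs_", id, ".csv")))
  }
  invisible(dir)
}

#' Read a cohort directory
#'
#' Reads everything [writeCohort()] writes, reassembling an
#' [ActivityCohort]; the truth table is attached when present.
#'
#' @param dir directory containing `metadata.csv`, `epochs_<id>.csv` and
#'   optionally `diary.csv` / `truth.csv`.
#' @param epochMinutes expected epoch spacing (`NULL` to infer per file).
#' @return an [ActivityCohort].
#' @export
readCohort <- function(dir, epochMinutes = NULL) {
  meta <- read.csv(file.path(dir, "metadata.csv"), stringsAsFactors = FALSE)
  meta$id <- as.character(meta$id)
  seriesList <- list()
  for (id in meta$id) {
    f <- file.path(dir, paste0("epochs_", id, ".csv"))
    if (!file.exists(f)) stop("missing epoch file for subject ", id,
                              call. = FALSE)
    seriesList[[id]] <- readEpochCSV(f, epochMinutes, subjectId = id)
  }
  diaryPath <- file.path(dir, "diary.csv")
  diary <- if (file.exists(diaryPath)) {
    d <- read.csv(diaryPath, stringsAsFactors = FALSE)
    d$id <- as.character(d$id)
    d$date <- as.Date(d$date)
    d
  } else emptyDiary()
  truthPath <- file.path(dir, "truth.csv")
  truth <- if (file.exists(truthPath)) {
    read.csv(truthPath, stringsAsFactors = FALSE)
  } else data.frame()
  activityCohort(meta, seriesList, diary, truth)
}

#' Per-subject quality-control summary
#'
#' One row per subject: recording length, missingness, diary coverage, and
#' whether metadata are complete. Collar-off spans are treated as missing
#' data (excluded from all averages), never as zero activity; the
#' `pct_missing` column is the share of epochs so flagged.
#'
#' @param cohort an [ActivityCohort].
#' @return a data.frame, one row per subject.
#' @export
validateCohort <- function(cohort) {
  meta <- subjects(cohort)
  diary <- diaries(cohort)
  rows <- lapply(meta$id, function(id) {
    s <- series(cohort, id)
    data.frame(
      id = id,
      n_epochs = length(s),
      days = length(s) * s@epochMinutes / MINUTES_PER_DAY,
      pct_missing = round(100 * mean(isMissing(s)), 2),
      diary_nights = sum(diary$id == id),
      age = meta$age[meta$id == id],
      sex = meta$sex[meta$id == id],
      mass = meta$mass[meta$id == id])
  })
  do.call(rbind, rows)
}
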