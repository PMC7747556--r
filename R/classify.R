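# Day/night classification from bedtime diaries, and per-day activity
# summaries feeding the mixed models.
#
# Night attribution: a night belongs to the calendar date on which the
# bedtime falls; its daytime complement spans that date's waketime to its
# bedtime. All intervals are half-open on the circular clock.

#' Label every epoch of a series as day or night
#'
#' Nighttime is the half-open window `[bedtime, waketime)` from the
#' subject's diary, wrapping midnight; every other epoch is daytime. Each
#' night is attributed to the calendar date of its bedtime (`stratumDate`),
#' and daytime epochs to their own calendar date, so repeated summaries
#' line up with diary nights.
#'
#' When a date has no diary entry the default window is applied with a
#' warning; a waketime missing from a diary row defaults to bedtime + 9 h.
#'
#' @param series an [EpochSeries].
#' @param windows data.frame with columns date, bedtime, waketime ("HH:MM")
#'   for this subject; may be empty.
#' @param defaultBedtime,defaultWaketime fallback window, "HH:MM".
#' @return data.frame with one row per epoch: `time`, `date`, `minute`
#'   (clock minute), `label` ("day"/"night"), `stratumDate`, `missing`;
#'   the per-date windows actually applied are attached as
#'   `attr(, "windows")` (minutes since midnight).
#' @export
classifyDayNight <- function(series, windows = NULL,
                             defaultBedtime = "22:00",
                             defaultWaketime = "07:00") {
  clock <- epochClock(series)
  dates <- clock$date
  minute <- clock$minute
  times <- epochTimes(series)

  allDates <- sort(unique(c(dates, dates - 1L)))  # night may start the day before
  if (is.null(windows) || nrow(windows) == 0L) {
    windows <- data.frame(date = as.Date(character()), bedtime = character(),
                          waketime = character())
  }
  windows$date <- as.Date(windows$date)
  if (anyDuplicated(windows$date)) {
    stop("overlapping night windows: duplicate diary entries for ",
         windows$date[anyDuplicated(windows$date)], call. = FALSE)
  }
  missingDates <- setdiff(as.character(allDates), as.character(windows$date))
  if (length(missingDates) > 0L && length(series) > 0L) {
    warning("no diary entry for ", length(missingDates),
            " date(s); applying default window ", defaultBedtime, "-",
            defaultWaketime, call. = FALSE)
  }
  bed <- setNames(rep(clockToMinutes(defaultBedtime), length(allDates)),
                  as.character(allDates))
  wake <- setNames(rep(clockToMinutes(defaultWaketime), length(allDates)),
                   as.character(allDates))
  if (nrow(windows)) {
    hasWake <- !is.na(windows$waketime) & nzchar(as.character(windows$waketime))
    b <- clockToMinutes(windows$bedtime)
    w <- ifelse(hasWake, clockToMinutes(as.character(windows$waketime)),
                (b + 9 * 60) %% MINUTES_PER_DAY)
    keep <- as.character(windows$date) %in% names(bed)
    bed[as.character(windows$date)[keep]] <- b[keep]
    wake[as.character(windows$date)[keep]] <- w[keep]
  }

  label <- rep("day", length(times))
  stratumDate <- dates
  key <- as.character(dates)
  keyPrev <- as.character(dates - 1L)
  bToday <- bed[key]; wToday <- wake[key]
  bPrev <- bed[keyPrev]; wPrev <- wake[keyPrev]
  # night started today: before-midnight portion (wrapping window) or the
  # whole window when it does not cross midnight
  nightToday <- ifelse(bToday > wToday, minute >= bToday,
                       minute >= bToday & minute < wToday)
  # night started yesterday, wrapped past midnight into today
  nightPrev <- bPrev > wPrev & minute < wPrev
  label[nightToday | nightPrev] <- "night"
  stratumDate[nightPrev] <- dates[nightPrev] - 1L

  out <- data.frame(time = times, date = dates, minute = minute,
                    label = label, stratumDate = stratumDate,
                    missing = isMissing(series))
  attr(out, "windows") <- data.frame(date = allDates, bedtime = unname(bed),
                                     waketime = unname(wake))
  out
}

#' Per-day mean day and night activity
#'
#' For each calendar stratum (a date's daytime, or the night beginning at
#' that date's bedtime), the mean count over non-missing epochs. A stratum
#' with more than `maxMissing` of its window missing or unrecorded yields
#' `NA`. `day_type` is weekday/weekend from the stratum date.
#'
#' @param series an [EpochSeries].
#' @param labels output of [classifyDayNight()] for the same series;
#'   computed with defaults when `NULL`.
#' @param maxMissing maximum tolerated missing fraction per stratum-day.
#' @return data.frame with columns `subject`, `date`, `day_type`,
#'   `daytime_mean`, `nighttime_mean` (NA where a stratum was dropped).
#' @export
summarizeActivity <- function(series, labels = NULL, maxMissing = 0.5) {
  if (is.null(labels)) labels <- classifyDayNight(series)
  win <- attr(labels, "windows")
  counts <- series@counts
  epm <- series@epochMinutes

  nightLen <- function(d) {          # expected night epochs for stratum date d
    i <- match(d, win$date)
    if (is.na(i)) return(0)
    clockWindowLength(win$bedtime[i], win$waketime[i]) / epm
  }
  dayLen <- function(d) {            # expected day epochs on calendar date d
    i <- match(d, win$date); iprev <- match(d - 1L, win$date)
    coverToday <- if (is.na(i)) 0 else {
      if (win$bedtime[i] > win$waketime[i]) MINUTES_PER_DAY - win$bedtime[i]
      else win$waketime[i] - win$bedtime[i]
    }
    coverPrev <- if (!is.na(iprev) && win$bedtime[iprev] > win$waketime[iprev])
      win$waketime[iprev] else 0
    (MINUTES_PER_DAY - coverToday - coverPrev) / epm
  }
  stratumMean <- function(rows, expected) {
    present <- rows[!labels$missing[rows]]
    if (length(present) < (1 - maxMissing) * expected || expected <= 0)
      return(NA_real_)
    mean(counts[present])
  }

  out <- lapply(split(seq_len(nrow(labels)), labels$stratumDate), function(idx) {
    date <- labels$stratumDate[idx[1L]]
    data.frame(
      subject = subjectId(series), date = date,
      day_type = if (isWeekend(date)) "weekend" else "weekday",
      daytime_mean = stratumMean(idx[labels$label[idx] == "day"], dayLen(date)),
      nighttime_mean = stratumMean(idx[labels$label[idx] == "night"],
                                   nightLen(date)))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[!(is.na(res$daytime_mean) & is.na(res$nighttime_mean)), , drop = FALSE]
}
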