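# Internal helpers: clock arithmetic and seed scoping.
#
# All clock arithmetic is on minutes-since-midnight integers with half-open
# intervals; a day has 1440 minutes.

MINUTES_PER_DAY <- 1440L

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores (or removes) the global `.Random.seed` afterwards, so functions
#' taking an explicit `seed` argument are pure functions of their inputs and
#' do not disturb the caller's RNG stream.
#' @noRd
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) {
      old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Parse "HH:MM" (or "HH:MM:SS") clock strings to minutes since midnight
#' @noRd
clockToMinutes <- function(x) {
  if (is.numeric(x)) {
    return(as.numeric(x) %% MINUTES_PER_DAY)
  }
  parts <- strsplit(as.character(x), ":", fixed = TRUE)
  vapply(parts, function(p) {
    if (length(p) < 2L || anyNA(suppressWarnings(as.numeric(p)))) {
      stop("unparsable clock time: ", paste(p, collapse = ":"), call. = FALSE)
    }
    (as.numeric(p[1L]) * 60 + as.numeric(p[2L])) %% MINUTES_PER_DAY
  }, numeric(1))
}

#' Format minutes since midnight as "HH:MM"
#' @noRd
minutesToClock <- function(m) {
  m <- round(as.numeric(m)) %% MINUTES_PER_DAY
  sprintf("%02d:%02d", m %/% 60L, m %% 60L)
}

#' Circular interval membership on the 24-h clock (half-open [from, to))
#'
#' Wraps midnight when `to <= from`; all arguments in minutes since midnight.
#' @noRd
inClockWindow <- function(minute, from, to) {
  minute <- minute %% MINUTES_PER_DAY
  from <- from %% MINUTES_PER_DAY
  to <- to %% MINUTES_PER_DAY
  if (from < to) minute >= from & minute < to else minute >= from | minute < to
}

#' Length of a circular [from, to) window in minutes
#' @noRd
clockWindowLength <- function(from, to) {
  (to - from) %% MINUTES_PER_DAY
}

# Clock minute and calendar date of every epoch, by integer arithmetic from
# the series start (UTC; avoids per-epoch timestamp formatting).
epochClock <- function(series) {
  startMin <- as.integer(format(series@start, "%H", tz = "UTC")) * 60L +
    as.integer(format(series@start, "%M", tz = "UTC"))
  abs <- startMin + (seq_along(series@counts) - 1L) * series@epochMinutes
  list(minute = abs %% MINUTES_PER_DAY,
       date = as.Date(series@start, tz = "UTC") + abs %/% MINUTES_PER_DAY)
}

isWeekend <- function(dates) {
  format(as.Date(dates), "%u") %in% c("6", "7")
}

stopIfNotFinite <- function(x, what) {
  if (!all(is.finite(x))) {
    stop(what, " must be finite", call. = FALSE)
  }
  invisible(x)
}
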