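#' Day segments
#'
#' The consensus metric set is evaluated over three clock windows: the whole
#' day `[00:00, 24:00)`, daytime `[06:00, 24:00)` and nighttime
#' `[00:00, 06:00)`. Windows are half-open, so a reading stamped exactly at
#' midnight belongs to the nighttime of the new day.
#'
#' @param name One of `"whole_day"`, `"daytime"`, `"nighttime"`.
#' @return A `day_segment` list with `name`, `start_min`, `end_min` (minutes
#'   after midnight) and `minutes` (window length).
#' @export
day_segment <- function(name = c("whole_day", "daytime", "nighttime")) {
  name <- match.arg(name)
  win <- switch(name,
                whole_day = c(0L, 1440L),
                daytime   = c(360L, 1440L),
                nighttime = c(0L, 360L))
  structure(list(name = name, start_min = win[[1L]], end_min = win[[2L]],
                 minutes = win[[2L]] - win[[1L]]),
            class = "day_segment")
}

DAY_SEGMENTS <- c("whole_day", "daytime", "nighttime")

#' Resolve a review period from a review date
#'
#' Three weekly conventions are supported. `week_ending_sunday` (the clinic
#' default) is the 7-day Monday-to-Sunday window whose final day is the last
#' Sunday strictly before the review date — reviewing on a Sunday therefore
#' looks back to the previous week. `trailing_7_days` is the 7 calendar days
#' before the review date. `week_starting_sunday` is the last full
#' Sunday-to-Saturday week ending on or before the review date, the
#' convention used for longitudinal cohort evaluation.
#'
#' @param review_date Date of the data review.
#' @param mode Period convention.
#' @return A `review_period` list with POSIXct `start` (inclusive), `end`
#'   (exclusive), the `mode`, and `days = 7`.
#' @export
#' @examples
#' resolve_review_period(as.Date("2020-02-07"), "week_ending_sunday")
resolve_review_period <- function(review_date,
                                  mode = c("week_ending_sunday",
                                           "trailing_7_days",
                                           "week_starting_sunday")) {
  mode <- match.arg(mode)
  d <- as_naive_date(review_date)
  if (mode == "trailing_7_days") {
    start <- d - 7L
  } else if (mode == "week_ending_sunday") {
    # last Sunday strictly before d; wday: 1 = Sunday
    offset <- ((lubridate::wday(d) - 1L) %% 7L)
    last_sunday <- d - ifelse(offset == 0L, 7L, offset)
    start <- last_sunday - 6L
  } else { # week_starting_sunday
    # last full [Sunday 00:00, Sunday 00:00) window ending on or before d
    offset <- (lubridate::wday(d) - 1L) %% 7L
    start <- d - offset - 7L
  }
  new_review_period(start, start + 7L, mode)
}

new_review_period <- function(start, end, mode = "explicit") {
  start <- as_naive_time(start)
  end <- as_naive_time(end)
  stopifnot(end > start)
  structure(list(start = start, end = end, mode = mode,
                 days = as.integer(round(as.double(end - start, units = "days")))),
            class = "review_period")
}

#' @export
print.review_period <- function(x, ...) {
  cat(sprintf("<review_period> [%s, %s) mode %s\n",
              fmt_ts(x$start), fmt_ts(x$end), x$mode))
  invisible(x)
}

#' Shift a review period backwards by whole weeks
#'
#' @param period A review period.
#' @param weeks Number of 7-day steps to shift back (positive).
#' @return A `review_period` of the same length.
#' @export
shift_period <- function(period, weeks = 1L) {
  new_review_period(period$start - weeks * 7L * 86400,
                    period$end - weeks * 7L * 86400, period$mode)
}

#' Maximum possible readings in a window
#'
#' The number of nominal sampling slots: a 5-minute sensor can record at most
#' 288 readings per whole day (96 for a 15-minute sensor). Used as the
#' denominator of the wear metric (ACT) and the valid-day rule.
#'
#' @param days Number of days in the window (a review period is 7).
#' @param segment A [day_segment()] or its name.
#' @param interval Nominal sampling interval, 5 or 15 minutes.
#' @return Integer count of sampling slots.
#' @export
#' @examples
#' max_possible_readings(1, "whole_day", 5)  # 288
#' max_possible_readings(7, "nighttime", 5)  # 504
max_possible_readings <- function(days, segment = "whole_day", interval = 5L) {
  if (!interval %in% c(5L, 15L)) abort("interval must be 5 or 15 minutes")
  if (is.character(segment)) segment <- day_segment(segment)
  as.integer(segment$minutes * days / interval)
}

undefined_metrics <- function(n_possible, days_active = 0L) {
  tibble(n_valid = 0L, n_possible = as.integer(n_possible),
         act_pct = 0, mean_glucose = NA_real_, tir_pct = NA_real_,
         hyp_pct = NA_real_, ehyp_pct = NA_real_, tar_pct = NA_real_,
         days_active = as.integer(days_active))
}

# Readings of `series` inside `period`, restricted to the segment clock window.
readings_in_window <- function(series, period, segment) {
  ts <- series$timestamp
  keep <- ts >= period$start & ts < period$end
  if (segment$name != "whole_day") {
    mins <- lubridate::hour(ts) * 60L + lubridate::minute(ts)
    keep <- keep & mins >= segment$start_min & mins < segment$end_min
  }
  series_keep_rows(series, keep)
}

#' Consensus CGM metrics for one patient, period and day segment
#'
#' Filters the series to the period and segment clock window, then computes
#' the consensus bundle: valid-reading count, wear percentage
#' (`act_pct = 100 * n_valid / n_possible`), mean glucose (mg/dL), time in
#' range (70--180 mg/dL inclusive), hypoglycemia (< 70 mg/dL), extreme
#' hypoglycemia (< 54 mg/dL), time above range (> 180 mg/dL), and the number
#' of days meeting the valid-day rule. `{Hyp, TIR, TAR}` partition the valid
#' readings, so their percentages sum to 100.
#'
#' With zero readings in the window, all glucose-derived fields are `NA`
#' ("no data" — deliberately distinct from 0) and `act_pct` is 0.
#'
#' @param series A [cgm_series()].
#' @param period A `review_period`.
#' @param segment A [day_segment()] or its name.
#' @param min_day_fraction Valid-day rule threshold for `days_active`.
#' @return A one-row tibble of class `period_metrics`.
#' @export
compute_period_metrics <- function(series, period,
                                   segment = "whole_day",
                                   min_day_fraction = 0.70) {
  if (is.character(segment)) segment <- day_segment(segment)
  interval <- series_interval(series) %||% 5L
  n_possible <- max_possible_readings(period$days, segment, interval)
  win <- readings_in_window(series, period, segment)
  n_valid <- nrow(win)

  whole <- readings_in_window(series, period, day_segment("whole_day"))
  days_active <- if (nrow(whole) == 0L) 0L else {
    per_day <- table(as.character(lubridate::as_date(whole$timestamp)))
    slots <- max_possible_readings(1L, "whole_day", interval)
    sum(per_day / slots >= min_day_fraction)
  }

  if (n_valid == 0L) {
    out <- undefined_metrics(n_possible, days_active)
  } else {
    g <- win$glucose
    out <- tibble(
      n_valid = n_valid,
      n_possible = n_possible,
      act_pct = 100 * n_valid / n_possible,
      mean_glucose = mean(g),
      tir_pct = 100 * mean(g >= 70 & g <= 180),
      hyp_pct = 100 * mean(g < 70),
      ehyp_pct = 100 * mean(g < 54),
      tar_pct = 100 * mean(g > 180),
      days_active = as.integer(days_active)
    )
  }
  class(out) <- c("period_metrics", class(out))
  out
}

#' Fraction of a calendar day's sampling slots with a valid reading
#'
#' @param series A [cgm_series()].
#' @param day A calendar date.
#' @return Fraction in `[0, 1]`.
#' @export
valid_day_fraction <- function(series, day) {
  day <- as_naive_date(day)
  interval <- series_interval(series) %||% 5L
  slots <- max_possible_readings(1L, "whole_day", interval)
  n <- sum(lubridate::as_date(series$timestamp) == day)
  n / slots
}

#' Drop days failing the valid-day rule
#'
#' A cohort-analysis day is included when at least `min_fraction` of the
#' day's nominal sampling slots have a valid reading (default 70%). Readings
#' on failing days are removed; the comparison is `>=`.
#'
#' @param series A [cgm_series()].
#' @param min_fraction Minimum fraction of possible readings (default 0.70).
#' @return The filtered [cgm_series()].
#' @export
filter_valid_days <- function(series, min_fraction = 0.70) {
  stopifnot(min_fraction >= 0, min_fraction <= 1)
  if (nrow(series) == 0L) return(series)
  interval <- series_interval(series) %||% 5L
  slots <- max_possible_readings(1L, "whole_day", interval)
  day <- lubridate::as_date(series$timestamp)
  per_day <- stats::ave(seq_along(day), as.character(day), FUN = length)
  series_keep_rows(series, per_day / slots >= min_fraction)
}
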