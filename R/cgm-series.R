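#' Canonical per-patient CGM series
#'
#' A `cgm_series` is a tibble with columns `timestamp` (naive local wall-clock
#' time, stored as POSIXct without meaningful zone) and `glucose` (mg/dL),
#' strictly increasing in `timestamp`, carrying the patient identifier and the
#' nominal sensor sampling interval (5 or 15 minutes) as attributes.
#'
#' @param patient_id Opaque patient identifier (length-1 character).
#' @param timestamp Reading times; anything [lubridate::ymd_hms()] parses, a
#'   `Date`, or a `POSIXct`. Treated as timezone-free clinic time.
#' @param glucose Glucose concentrations in mg/dL (positive, finite).
#' @param interval_min Nominal sampling interval in minutes (5 or 15). When
#'   `NULL` it is inferred from the timestamps via
#'   [infer_sampling_interval()] (requires at least two readings).
#'
#' @return A `cgm_series` object.
#' @export
#' @examples
#' s <- cgm_series("p1", as.POSIXct("2020-01-05") + 300 * (0:5), rep(100, 6))
#' series_interval(s)
cgm_series <- function(patient_id, timestamp, glucose, interval_min = NULL) {
  stopifnot(length(patient_id) == 1L)
  ts <- as_naive_time(timestamp)
  if (anyNA(ts)) abort("unparseable timestamp in series construction")
  glucose <- as.double(glucose)
  if (any(!is.finite(glucose)) || any(glucose <= 0)) {
    abort("glucose values must be finite and > 0 (mg/dL)")
  }
  readings <- deduplicate_and_sort(tibble(timestamp = ts, glucose = glucose))
  if (!is.null(interval_min)) {
    interval_min <- as.integer(interval_min)
    if (!interval_min %in% c(5L, 15L)) {
      abort("interval_min must be 5 or 15 minutes")
    }
  }
  new_cgm_series(readings, patient_id = as.character(patient_id),
                 interval_min = interval_min)
}

new_cgm_series <- function(readings, patient_id, interval_min = NULL) {
  out <- as_tibble(readings)
  attr(out, "patient_id") <- patient_id
  if (is.null(interval_min) && nrow(out) >= 2L) {
    interval_min <- infer_interval_from_diffs(out$timestamp)
  }
  attr(out, "interval_min") <- interval_min
  class(out) <- c("cgm_series", class(tibble()))
  out
}

#' @rdname cgm_series
#' @param x A `cgm_series`.
#' @export
series_patient_id <- function(x) attr(x, "patient_id")

#' @rdname cgm_series
#' @export
series_interval <- function(x) attr(x, "interval_min")

#' @export
print.cgm_series <- function(x, ...) {
  cat(sprintf("<cgm_series> patient %s, %d readings, nominal interval %s min\n",
              series_patient_id(x), nrow(x),
              series_interval(x) %||% "?"))
  NextMethod()
}

# Rebuild series attributes after a dplyr-style row filter.
series_keep_rows <- function(series, keep) {
  new_cgm_series(as_tibble(series)[keep, , drop = FALSE],
                 patient_id = series_patient_id(series),
                 interval_min = series_interval(series))
}

#' A cohort of CGM series
#'
#' A `cgm_cohort` is a named list of [cgm_series()] objects, keyed by patient
#' identifier.
#'
#' @param series A list of `cgm_series` objects.
#' @return A `cgm_cohort`.
#' @export
cgm_cohort <- function(series) {
  stopifnot(is.list(series))
  ok <- vapply(series, inherits, logical(1), what = "cgm_series")
  if (!all(ok)) abort("all elements must be cgm_series objects")
  ids <- vapply(series, series_patient_id, character(1))
  if (anyDuplicated(ids)) abort("duplicate patient ids in cohort")
  names(series) <- ids
  structure(series, class = "cgm_cohort")
}

#' @export
print.cgm_cohort <- function(x, ...) {
  n_read <- sum(vapply(x, nrow, integer(1)))
  cat(sprintf("<cgm_cohort> %d patients, %d readings\n", length(x), n_read))
  invisible(x)
}

#' @export
`[.cgm_cohort` <- function(x, i) {
  cgm_cohort(unclass(x)[i])
}

#' Convert glucose concentrations to mg/dL
#'
#' mg/dL values pass through unchanged; mmol/L values are multiplied by
#' 18.0182 (the standard glucose molar-mass factor) and rounded to one
#' decimal. Vectorized over both arguments.
#'
#' @param value Positive glucose concentrations.
#' @param unit `"mg/dL"` or `"mmol/L"` (recycled against `value`).
#' @return Concentrations in mg/dL.
#' @export
#' @examples
#' normalize_units(10, "mmol/L") # 180.2
normalize_units <- function(value, unit) {
  value <- as.double(value)
  if (any(!is.finite(value)) || any(value <= 0)) {
    abort("glucose values must be finite and > 0")
  }
  unit <- rep_len(as.character(unit), length(value))
  known <- unit %in% c("mg/dL", "mmol/L")
  if (!all(known)) {
    abort(sprintf("unknown glucose unit label: %s",
                  paste(unique(unit[!known]), collapse = ", ")))
  }
  out <- value
  mm <- unit == "mmol/L"
  out[mm] <- round(value[mm] * MMOL_TO_MGDL, 1)
  out
}

#' Sort readings and collapse duplicate timestamps
#'
#' Readings are stably sorted by timestamp; when a timestamp occurs more than
#' once the first-seen value (in input order) is kept and a warning reports
#' the number dropped. The result has strictly increasing timestamps.
#'
#' @param readings A data frame with `timestamp` and `glucose` columns.
#' @return A tibble with strictly increasing `timestamp`.
#' @export
deduplicate_and_sort <- function(readings) {
  readings <- as_tibble(readings)[, c("timestamp", "glucose")]
  if (nrow(readings) == 0L) return(readings)
  readings <- readings[order(readings$timestamp, method = "radix"), ]
  dup <- duplicated(readings$timestamp)
  if (any(dup)) {
    warn(sprintf("dropped %d duplicate-timestamp reading(s); first-seen kept",
                 sum(dup)))
    readings <- readings[!dup, ]
  }
  readings
}

infer_interval_from_diffs <- function(timestamps) {
  d <- as.double(diff(timestamps), units = "mins")
  med <- stats::median(d)
  # snap to the nearer of 5 / 15 minutes; the midpoint (10) goes to 5
  if (med <= 10) 5L else 15L
}

#' Infer the nominal sampling interval of a series
#'
#' Takes the median of successive timestamp differences (robust to sensor
#' wear gaps) and snaps it to the nearer of the two interval classes CGM
#' hardware uses, 5 or 15 minutes, breaking the midpoint toward 5.
#'
#' @param series A [cgm_series()] with at least two readings.
#' @return 5 or 15 (integer minutes).
#' @export
infer_sampling_interval <- function(series) {
  if (nrow(series) < 2L) abort("interval not inferable: fewer than 2 readings")
  infer_interval_from_diffs(series$timestamp)
}
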