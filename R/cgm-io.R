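#' Column-mapping dialect for a CGM export
#'
#' Devices and aggregator platforms export CGM data with different column
#' names, delimiters and timestamp formats. A dialect declares where the
#' three mandatory fields live; nothing is auto-sniffed. The canonical
#' dialect is the package's own: header `patient_id,timestamp,glucose,unit`
#' with ISO-8601 timestamps.
#'
#' @param patient_col,time_col,glucose_col Names of the mandatory columns.
#' @param unit_col Name of the unit column, or `NULL` when the file carries
#'   no unit column (then `default_unit` applies to every row).
#' @param default_unit Unit label assumed when `unit_col` is `NULL` or a
#'   row's unit cell is empty.
#' @param ts_format A [base::strptime()] format for the timestamp column, or
#'   `NULL` for ISO-8601 (date, `T` or space, time; seconds optional).
#' @param delim Field delimiter.
#' @return A `cgm_dialect` list.
#' @export
cgm_dialect <- function(patient_col = "patient_id", time_col = "timestamp",
                        glucose_col = "glucose", unit_col = "unit",
                        default_unit = "mg/dL", ts_format = NULL,
                        delim = ",") {
  structure(list(patient_col = patient_col, time_col = time_col,
                 glucose_col = glucose_col, unit_col = unit_col,
                 default_unit = default_unit, ts_format = ts_format,
                 delim = delim),
            class = "cgm_dialect")
}

parse_dialect_time <- function(x, ts_format) {
  if (is.null(ts_format)) {
    lubridate::ymd_hms(x, tz = "UTC", truncated = 3, quiet = TRUE)
  } else {
    as.POSIXct(strptime(x, format = ts_format, tz = "UTC"), tz = "UTC")
  }
}

#' Read a CGM export into a cohort of canonical series
#'
#' Reads a delimited text file (one patient or long-format population),
#' normalizes glucose to mg/dL, collapses duplicate timestamps (first-seen
#' wins), sorts, and returns one [cgm_series()] per distinct patient.
#'
#' @param path Path to a delimited text file.
#' @param dialect A [cgm_dialect()] describing the columns.
#' @return A [cgm_cohort()] (possibly empty, with a warning, for an empty
#'   file).
#' @export
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("patient_id,timestamp,glucose,unit",
#'              "p1,2020-01-05T00:00:00,100,mg/dL",
#'              "p1,2020-01-05T00:05:00,110,mg/dL"), f)
#' read_cgm_table(f)
read_cgm_table <- function(path, dialect = cgm_dialect()) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  raw <- readr::read_delim(path, delim = dialect$delim,
                           col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
  needed <- c(dialect$patient_col, dialect$time_col, dialect$glucose_col)
  missing <- setdiff(needed, names(raw))
  if (length(missing) > 0L) {
    abort(sprintf("%s: missing mandatory column(s): %s", path,
                  paste(missing, collapse = ", ")))
  }
  if (nrow(raw) == 0L) {
    warn(sprintf("%s: no data rows; returning empty cohort", path))
    return(cgm_cohort(list()))
  }

  ts <- parse_dialect_time(raw[[dialect$time_col]], dialect$ts_format)
  bad <- which(is.na(ts))
  if (length(bad) > 0L) {
    abort(sprintf("%s: unparseable timestamp at data row(s) %s", path,
                  paste(utils::head(bad, 5L), collapse = ", ")))
  }
  unit <- if (!is.null(dialect$unit_col) && dialect$unit_col %in% names(raw)) {
    u <- raw[[dialect$unit_col]]
    ifelse(is.na(u) | u == "", dialect$default_unit, u)
  } else {
    rep(dialect$default_unit, nrow(raw))
  }
  glucose <- suppressWarnings(as.double(raw[[dialect$glucose_col]]))
  bad <- which(!is.finite(glucose))
  if (length(bad) > 0L) {
    abort(sprintf("%s: non-numeric glucose at data row(s) %s", path,
                  paste(utils::head(bad, 5L), collapse = ", ")))
  }
  glucose <- normalize_units(glucose, unit)

  long <- tibble(patient_id = as.character(raw[[dialect$patient_col]]),
                 timestamp = ts, glucose = glucose)
  series <- lapply(split(long, long$patient_id), function(df) {
    cgm_series(df$patient_id[[1L]], df$timestamp, df$glucose)
  })
  cgm_cohort(unname(series))
}

#' Write series in the canonical CSV dialect
#'
#' Writes `patient_id,timestamp,glucose,unit` with ISO-8601 timestamps and
#' unit mg/dL, so that [read_cgm_table()] round-trips the data exactly.
#'
#' @param x A [cgm_series()] or [cgm_cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cgm_table <- function(x, path) {
  if (inherits(x, "cgm_series")) x <- cgm_cohort(list(x))
  stopifnot(inherits(x, "cgm_cohort"))
  rows <- purrr::map_dfr(x, function(s) {
    tibble(patient_id = series_patient_id(s),
           timestamp = fmt_ts(s$timestamp),
           glucose = s$glucose,
           unit = "mg/dL")
  })
  if (nrow(rows) == 0L) {
    rows <- tibble(patient_id = character(), timestamp = character(),
                   glucose = double(), unit = character())
  }
  readr::write_csv(rows, path, progress = FALSE)
  invisible(path)
}

#' Read every canonical CSV in a directory as one cohort
#'
#' @param dir Directory containing canonical-dialect CSV files.
#' @param dialect Dialect shared by all files.
#' @return A [cgm_cohort()] pooling all patients found.
#' @export
read_cgm_dir <- function(dir, dialect = cgm_dialect()) {
  if (!dir.exists(dir)) abort(sprintf("directory not found: %s", dir))
  files <- list.files(dir, pattern = "\\.(csv|tsv)$", full.names = TRUE)
  cohorts <- lapply(files, read_cgm_table, dialect = dialect)
  cgm_cohort(unlist(lapply(cohorts, unclass), recursive = FALSE))
}
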