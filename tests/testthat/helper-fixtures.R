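# A Sunday, so weekly windows of both conventions align cleanly.
SUNDAY0 <- as.Date("2020-01-05")

t0 <- function(date = SUNDAY0) as.POSIXct(as.character(date), tz = "UTC")

# Regular 5-minute series of constant (or supplied) glucose over n_days.
make_series <- function(values = 100, n_days = 7, id = "p1",
                        start = SUNDAY0, interval = 5L) {
  per_day <- 1440L %/% interval
  n <- n_days * per_day
  ts <- t0(start) + (seq_len(n) - 1L) * interval * 60
  cgm_series(id, ts, rep_len(values, n), interval_min = interval)
}

new_period_for_test <- function(start, days = 7L) {
  cgmtriage:::new_review_period(t0(start), t0(start) + days * 86400)
}

write_cohort_csv <- function(cohort, path = tempfile(fileext = ".csv")) {
  write_cgm_table(cohort, path)
  path
}
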