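# Independent brute-force oracles, written as plain scans with literal
# thresholds. They deliberately share no code with the package's metric or
# flag implementations.

# Classify every reading one at a time against the literal thresholds.
# `seg_min` is c(start, end) in minutes after midnight.
oracle_scan <- function(series, start, end, seg_min = c(0L, 1440L),
                        interval = 5L) {
  g <- series$glucose
  lt <- as.POSIXlt(series$timestamp, tz = "UTC")
  mins <- lt$hour * 60L + lt$min
  ts <- as.numeric(series$timestamp) # plain seconds: fast scalar comparisons
  start <- as.numeric(start); end <- as.numeric(end)
  n <- 0L; total <- 0
  n_tir <- 0L; n_hyp <- 0L; n_ehyp <- 0L; n_tar <- 0L
  for (i in seq_along(g)) {
    if (ts[i] >= start && ts[i] < end &&
        mins[i] >= seg_min[1L] && mins[i] < seg_min[2L]) {
      n <- n + 1L
      total <- total + g[i]
      if (g[i] < 54) n_ehyp <- n_ehyp + 1L
      if (g[i] < 70) {
        n_hyp <- n_hyp + 1L
      } else if (g[i] <= 180) {
        n_tir <- n_tir + 1L
      } else {
        n_tar <- n_tar + 1L
      }
    }
  }
  days <- (end - start) / 86400
  n_possible <- (seg_min[2L] - seg_min[1L]) * days / interval
  list(
    n_valid = n,
    n_possible = n_possible,
    act_pct = 100 * n / n_possible,
    mean_glucose = if (n == 0L) NA_real_ else total / n,
    tir_pct = if (n == 0L) NA_real_ else 100 * n_tir / n,
    hyp_pct = if (n == 0L) NA_real_ else 100 * n_hyp / n,
    ehyp_pct = if (n == 0L) NA_real_ else 100 * n_ehyp / n,
    tar_pct = if (n == 0L) NA_real_ else 100 * n_tar / n
  )
}

# Per-day reading census: counts readings on each calendar day present.
oracle_day_census <- function(series) {
  days <- as.Date(format(series$timestamp, "%Y-%m-%d"))
  table(days)
}

segment_minutes <- list(whole_day = c(0L, 1440L),
                        daytime = c(360L, 1440L),
                        nighttime = c(0L, 360L))

# Calendar oracle: last Sunday strictly before `d`, found by walking back
# one day at a time.
oracle_last_sunday_before <- function(d) {
  x <- d - 1
  while (format(x, "%u") != "7") x <- x - 1
  x
}
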