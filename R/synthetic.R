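#' Synthetic patient profile
#'
#' Parameters of one simulated CGM wearer. Glucose follows a stationary
#' first-order autoregressive process around `target_mean` with stationary
#' standard deviation `within_sd` and lag-one autocorrelation `phi` at the
#' sampling interval; whole days are dropped independently with probability
#' `1 - wear_prob` to emulate sensor wear gaps. Values are clipped to the
#' common CGM reportable range, 40--400 mg/dL.
#'
#' @param patient_id Identifier for the simulated patient.
#' @param target_mean Long-run mean glucose, mg/dL.
#' @param within_sd Stationary within-patient SD, mg/dL.
#' @param phi Lag-one autocorrelation at the sampling interval, in `[0, 1)`.
#' @param interval_min Sampling interval, 5 or 15 minutes.
#' @param wear_prob Probability a given day is worn (has any readings).
#' @param n_weeks Number of whole weeks to simulate.
#' @param start Date of the first simulated day (a Sunday keeps weekly
#'   windows aligned; the default is one).
#' @param seed RNG seed for this patient.
#' @return A `patient_profile` list.
#' @export
patient_profile <- function(patient_id = "sim", target_mean = 170,
                            within_sd = 55, phi = 0.7, interval_min = 5L,
                            wear_prob = 0.9, n_weeks = 8L,
                            start = as.Date("2020-01-05"), seed = 1L) {
  stopifnot(target_mean > 0, within_sd >= 0, phi >= 0, phi < 1,
            interval_min %in% c(5L, 15L), wear_prob >= 0, wear_prob <= 1,
            n_weeks >= 1L)
  structure(list(patient_id = as.character(patient_id),
                 target_mean = target_mean, within_sd = within_sd,
                 phi = phi, interval_min = as.integer(interval_min),
                 wear_prob = wear_prob, n_weeks = as.integer(n_weeks),
                 start = as_naive_date(start), seed = as.integer(seed)),
            class = "patient_profile")
}

#' Generate one synthetic patient series
#'
#' Fully reproducible from the profile's seed; the caller's RNG state is
#' left untouched.
#'
#' @param profile A [patient_profile()].
#' @return A [cgm_series()].
#' @export
generate_patient <- function(profile) {
  with_seed(profile$seed, {
    n_days <- profile$n_weeks * 7L
    per_day <- MINUTES_PER_DAY %/% profile$interval_min
    n <- n_days * per_day
    # stationary AR(1): innovations scaled so the marginal SD is within_sd
    eps_sd <- profile$within_sd * sqrt(1 - profile$phi^2)
    x <- double(n)
    x[1L] <- stats::rnorm(1L, 0, profile$within_sd)
    if (n > 1L) {
      eps <- stats::rnorm(n - 1L, 0, eps_sd)
      for (i in 2L:n) x[i] <- profile$phi * x[i - 1L] + eps[i - 1L]
    }
    glucose <- pmin(pmax(profile$target_mean + x, CGM_CLIP_RANGE[[1L]]),
                    CGM_CLIP_RANGE[[2L]])
    worn <- stats::runif(n_days) <= profile$wear_prob
    ts <- as_naive_time(profile$start) +
      (rep(seq_len(n_days) - 1L, each = per_day) * 86400 +
         rep(seq_len(per_day) - 1L, times = n_days) *
           profile$interval_min * 60)
    keep <- rep(worn, each = per_day)
    cgm_series(profile$patient_id, ts[keep], glucose[keep],
               interval_min = profile$interval_min)
  })
}

#' Inject a step-change deterioration event
#'
#' Shifts every reading on or after the onset by `delta_mean` (signed,
#' mg/dL) and re-clips to the reportable range — the minimal model of an
#' abrupt, sustained change in glucose control used to exercise the
#' personalized flag rules.
#'
#' @param series A [cgm_series()].
#' @param onset Date or datetime of the change.
#' @param delta_mean Signed shift in mg/dL.
#' @return The shifted [cgm_series()].
#' @export
inject_change <- function(series, onset, delta_mean) {
  onset <- as_naive_time(onset)
  if (nrow(series) > 0L &&
      (onset < min(series$timestamp) || onset > max(series$timestamp))) {
    abort("change onset lies outside the series span")
  }
  g <- series$glucose
  after <- series$timestamp >= onset
  g[after] <- pmin(pmax(g[after] + delta_mean, CGM_CLIP_RANGE[[1L]]),
                   CGM_CLIP_RANGE[[2L]])
  out <- as_tibble(series)
  out$glucose <- g
  new_cgm_series(out, patient_id = series_patient_id(series),
                 interval_min = series_interval(series))
}

#' Generate a synthetic cohort
#'
#' Draws per-patient target means from a truncated normal distribution
#' (emulating the large between-patient spread of real CGM populations,
#' whose data-set mean glucose ranges roughly 141--207 mg/dL), derives
#' per-patient seeds deterministically from the master seed, and optionally
#' injects a step-change event into a fixed number of patients.
#'
#' @param n_patients Cohort size.
#' @param cohort_mean,cohort_sd Mean and SD of the between-patient
#'   target-mean distribution, mg/dL (truncated to 70--350).
#' @param within_sd,phi,interval_min,wear_prob,n_weeks,start Passed to
#'   every [patient_profile()].
#' @param n_change Number of patients (the first `n_change` ids) receiving
#'   a step change.
#' @param change_delta Signed step size, mg/dL.
#' @param change_week Week (1-based) at whose start the change occurs.
#' @param seed Master seed.
#' @return A [cgm_cohort()]; changed patients have ids prefixed `chg`,
#'   stationary patients `pat`.
#' @export
generate_cohort <- function(n_patients, cohort_mean = 170, cohort_sd = 25,
                            within_sd = 55, phi = 0.7, interval_min = 5L,
                            wear_prob = 0.9, n_weeks = 8L,
                            start = as.Date("2020-01-05"),
                            n_change = 0L, change_delta = 25,
                            change_week = NULL, seed = 1L) {
  stopifnot(n_patients >= 1L, n_change >= 0L, n_change <= n_patients)
  if (is.null(change_week)) change_week <- n_weeks
  draws <- with_seed(seed, {
    list(means = stats::rnorm(n_patients, cohort_mean, cohort_sd),
         seeds = sample.int(.Machine$integer.max, n_patients))
  })
  means <- pmin(pmax(draws$means, 70), 350)
  series <- lapply(seq_len(n_patients), function(i) {
    changed <- i <= n_change
    id <- sprintf("%s%03d", if (changed) "chg" else "pat", i)
    s <- generate_patient(patient_profile(
      patient_id = id, target_mean = means[[i]], within_sd = within_sd,
      phi = phi, interval_min = interval_min, wear_prob = wear_prob,
      n_weeks = n_weeks, start = start, seed = draws$seeds[[i]]
    ))
    if (changed) {
      onset <- as_naive_date(start) + (change_week - 1L) * 7L
      s <- inject_change(s, onset, change_delta)
    }
    s
  })
  cgm_cohort(series)
}

#' Independent reference labeler
#'
#' A deliberately naive, straight-line reimplementation of the triage
#' decision, sharing no code with the metrics or flags modules: it scans
#' the raw readings in the review and baseline windows and applies the
#' literal thresholds. Used as the reference truth ("appropriate for
#' contact") when evaluating the pipeline with [confusion_metrics()].
#'
#' @param series A [cgm_series()].
#' @param period A review period.
#' @param config A [tool_config()].
#' @return `"appropriate"`, `"not_appropriate"`, or `"insufficient_data"`.
#' @export
oracle_label <- function(series, period, config = tool_config("simulation")) {
  interval <- series_interval(series) %||% 5L
  slots_per_day <- (24 * 60) %/% interval
  in_win <- function(t0, t1) {
    series$glucose[series$timestamp >= t0 & series$timestamp < t1]
  }
  g <- in_win(period$start, period$end)
  if (length(g) == 0L) return("insufficient_data")

  # valid-day census, written out longhand
  n_valid_days <- 0L
  for (d in 0:(period$days - 1L)) {
    d0 <- period$start + d * 86400
    nd <- length(in_win(d0, d0 + 86400))
    if (nd / slots_per_day >= config$valid_day_fraction) {
      n_valid_days <- n_valid_days + 1L
    }
  }
  if (n_valid_days < config$min_valid_days) return("insufficient_data")

  mg <- sum(g) / length(g)
  tir <- 100 * sum(g >= 70 & g <= 180) / length(g)
  hyp <- 100 * sum(g < 70) / length(g)
  ehyp <- 100 * sum(g < 54) / length(g)
  act <- 100 * length(g) / (slots_per_day * period$days)
  vals <- list(mean_glucose = mg, tir_pct = tir, hyp_pct = hyp,
               ehyp_pct = ehyp, act_pct = act)

  for (r in config$rules) {
    if (r$kind != "generic" || r$role != "alert") next
    v <- vals[[r$metric]]
    hit <- if (r$comparator == ">") v > r$threshold else v < r$threshold
    if (hit) return("appropriate")
  }

  # personalized: only with enough history before the period start
  first <- min(series$timestamp)
  weeks_hist <- floor(as.double(period$start - first, units = "days") / 7)
  if (weeks_hist >= config$base_spec$min_history_weeks) {
    b0 <- period$start - config$base_spec$n_weeks * 7L * 86400
    gb <- in_win(b0, period$start)
    if (length(gb) > 0L) {
      mgb <- sum(gb) / length(gb)
      tirb <- 100 * sum(gb >= 70 & gb <= 180) / length(gb)
      for (r in config$rules) {
        if (r$kind != "personalized") next
        if (r$metric == "mean_glucose" && r$comparator == ">" &&
            mg > mgb + r$threshold) return("appropriate")
        if (r$metric == "tir_pct" && r$comparator == "<" &&
            tir < tirb - r$threshold) return("appropriate")
      }
    }
  }
  "not_appropriate"
}
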