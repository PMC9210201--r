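#' Flag rules
#'
#' A flag rule compares one consensus metric against a threshold. Generic
#' rules use an absolute threshold applied identically to every patient
#' (e.g. mean glucose > 170 mg/dL). Personalized rules use a delta relative
#' to the patient's own baseline-period value (e.g. TIR more than 10
#' percentage points below baseline). All comparators are strict: a value
#' exactly at the threshold never triggers.
#'
#' @param metric One of `"mean_glucose"`, `"tir_pct"`, `"hyp_pct"`,
#'   `"ehyp_pct"`, `"act_pct"`. Personalized rules are defined only for
#'   `mean_glucose` and `tir_pct`.
#' @param kind `"generic"` or `"personalized"`.
#' @param comparator `">"` or `"<"`. For personalized rules, `">"` means the
#'   review value exceeds baseline + threshold; `"<"` means it falls below
#'   baseline - threshold.
#' @param threshold Absolute value (generic) or positive delta
#'   (personalized; mg/dL for mean glucose, percentage points for TIR).
#' @param role `"alert"` (promotes the patient to the alerts tab) or
#'   `"wear"` (an annotation only, used for the sensor-wear rule).
#' @return A `flag_rule` list.
#' @export
flag_rule <- function(metric, kind = c("generic", "personalized"),
                      comparator = c(">", "<"), threshold,
                      role = c("alert", "wear")) {
  kind <- match.arg(kind)
  comparator <- match.arg(comparator)
  role <- match.arg(role)
  known <- c("mean_glucose", "tir_pct", "hyp_pct", "ehyp_pct", "act_pct")
  if (!metric %in% known) {
    abort(sprintf("unknown metric in flag rule: %s", metric))
  }
  if (kind == "personalized" && !metric %in% c("mean_glucose", "tir_pct")) {
    abort("personalized rules are defined only for mean_glucose and tir_pct")
  }
  structure(list(metric = metric, kind = kind, comparator = comparator,
                 threshold = as.double(threshold), role = role),
            class = "flag_rule")
}

rule_id <- function(rule) {
  sprintf("%s_%s", rule$kind, rule$metric)
}

#' Built-in rule presets
#'
#' Two named presets ship with the package, reflecting the two settings the
#' thresholds were designed for:
#'
#' * `"clinic"` — the weekly pediatric-clinic review configuration: TIR
#'   < 60%, extreme hypoglycemia > 1%, hypoglycemia > 4%, a sensor-wear
#'   annotation when ACT < 75% (an annotation, not an alert), and a
#'   personalized TIR drop of more than 10 percentage points against a
#'   4-week baseline.
#' * `"simulation"` — the longitudinal-evaluation configuration: mean
#'   glucose > 170 mg/dL, TIR < 60%, extreme hypoglycemia > 1%,
#'   hypoglycemia > 3%, personalized mean glucose rise > 10 mg/dL and TIR
#'   drop > 10 points against the previous week.
#'
#' @param preset `"clinic"` or `"simulation"`.
#' @return A list of [flag_rule()] objects.
#' @export
rule_preset <- function(preset = c("clinic", "simulation")) {
  preset <- match.arg(preset)
  if (preset == "clinic") {
    list(
      flag_rule("tir_pct", "generic", "<", 60),
      flag_rule("ehyp_pct", "generic", ">", 1),
      flag_rule("hyp_pct", "generic", ">", 4),
      flag_rule("act_pct", "generic", "<", 75, role = "wear"),
      flag_rule("tir_pct", "personalized", "<", 10)
    )
  } else {
    list(
      flag_rule("mean_glucose", "generic", ">", 170),
      flag_rule("tir_pct", "generic", "<", 60),
      flag_rule("ehyp_pct", "generic", ">", 1),
      flag_rule("hyp_pct", "generic", ">", 3),
      flag_rule("mean_glucose", "personalized", ">", 10),
      flag_rule("tir_pct", "personalized", "<", 10)
    )
  }
}

#' Baseline specification for personalized flags
#'
#' The baseline period is the `n_weeks`-long window immediately preceding
#' the review period. Personalized flags are only evaluated for patients
#' with at least `min_history_weeks` weeks of data ending at the review
#' period's start.
#'
#' @param n_weeks Length of the baseline window in whole weeks.
#' @param min_history_weeks Minimum weeks of history required (default 4).
#' @return A `baseline_spec` list.
#' @export
baseline_spec <- function(n_weeks = 1L, min_history_weeks = 4L) {
  n_weeks <- as.integer(n_weeks)
  min_history_weeks <- as.integer(min_history_weeks)
  stopifnot(n_weeks >= 1L, min_history_weeks >= n_weeks)
  structure(list(n_weeks = n_weeks, min_history_weeks = min_history_weeks),
            class = "baseline_spec")
}

empty_flag_set <- function() {
  tibble(rule_id = character(), metric = character(), kind = character(),
         comparator = character(), threshold = double(),
         observed = double(), baseline = double(), role = character(),
         triggered = logical())
}

flag_row <- function(rule, observed, baseline, triggered) {
  tibble(rule_id = rule_id(rule), metric = rule$metric, kind = rule$kind,
         comparator = rule$comparator, threshold = rule$threshold,
         observed = observed, baseline = baseline, role = rule$role,
         triggered = triggered)
}

#' Evaluate generic flag rules against period metrics
#'
#' A rule triggers iff its metric is defined and the strict comparison
#' holds. Undefined ("no data") metrics never trigger.
#'
#' @param metrics A [compute_period_metrics()] row.
#' @param rules A list of generic [flag_rule()]s (e.g. from
#'   [rule_preset()]; personalized rules present in the list are ignored).
#' @return A flag-set tibble, one row per rule, with a `triggered` column.
#' @export
evaluate_generic_flags <- function(metrics, rules) {
  rules <- Filter(function(r) r$kind == "generic", rules)
  if (length(rules) == 0L) return(empty_flag_set())
  purrr::map_dfr(rules, function(rule) {
    obs <- metrics[[rule$metric]]
    trig <- if (is.na(obs)) FALSE else {
      if (rule$comparator == ">") obs > rule$threshold else obs < rule$threshold
    }
    flag_row(rule, observed = as.double(obs), baseline = NA_real_,
             triggered = trig)
  })
}

#' Weeks of history available before a time point
#'
#' @param series A [cgm_series()].
#' @param at POSIXct time point (typically a review period start).
#' @return Whole weeks (floored) between the earliest reading and `at`.
#' @export
history_weeks <- function(series, at) {
  if (nrow(series) == 0L) return(0L)
  span <- as.double(at - min(series$timestamp), units = "days")
  max(0L, as.integer(floor(span / 7)))
}

#' Baseline-period metrics for personalized flags
#'
#' Computes whole-day metrics over the baseline window (the
#' `spec$n_weeks`-week window immediately preceding the review period).
#' Returns `NULL` ("insufficient history") when the patient has fewer than
#' `spec$min_history_weeks` weeks of data ending at the period start, or
#' when the baseline window holds no readings.
#'
#' @param series A [cgm_series()].
#' @param period The review period the baseline precedes.
#' @param spec A [baseline_spec()].
#' @return A `period_metrics` row, or `NULL` for insufficient history.
#' @export
compute_baseline <- function(series, period, spec = baseline_spec()) {
  if (history_weeks(series, period$start) < spec$min_history_weeks) {
    return(NULL)
  }
  base_period <- new_review_period(period$start - spec$n_weeks * 7L * 86400,
                                   period$start, "baseline")
  m <- compute_period_metrics(series, base_period)
  if (m$n_valid == 0L) return(NULL)
  m
}

#' Evaluate personalized flag rules
#'
#' A `">"` rule triggers iff the review value strictly exceeds the baseline
#' value plus the delta threshold; a `"<"` rule iff it falls strictly below
#' the baseline minus the delta. With `baseline = NULL` (insufficient
#' history) or undefined review metrics, no personalized flag is emitted.
#'
#' @param review Review-period metrics.
#' @param baseline Baseline-period metrics, or `NULL`.
#' @param rules A list of personalized [flag_rule()]s (generic rules in the
#'   list are ignored).
#' @return A flag-set tibble (empty when `baseline` is `NULL`).
#' @export
evaluate_personalized_flags <- function(review, baseline, rules) {
  rules <- Filter(function(r) r$kind == "personalized", rules)
  if (length(rules) == 0L || is.null(baseline)) return(empty_flag_set())
  purrr::map_dfr(rules, function(rule) {
    obs <- review[[rule$metric]]
    base <- baseline[[rule$metric]]
    trig <- if (is.na(obs) || is.na(base)) FALSE else {
      if (rule$comparator == ">") obs > base + rule$threshold
      else obs < base - rule$threshold
    }
    flag_row(rule, observed = as.double(obs), baseline = as.double(base),
             triggered = trig)
  })
}

#' Evaluate every rule for one patient and period
#'
#' @param series A [cgm_series()].
#' @param period A review period.
#' @param rules A list of [flag_rule()]s (mixed kinds).
#' @param base_spec A [baseline_spec()].
#' @return A flag-set tibble combining generic and personalized rows.
#' @export
evaluate_flags <- function(series, period, rules, base_spec = baseline_spec()) {
  review <- compute_period_metrics(series, period)
  base <- compute_baseline(series, period, base_spec)
  dplyr::bind_rows(evaluate_generic_flags(review, rules),
                   evaluate_personalized_flags(review, base, rules))
}

#' Triage status of a patient for one review period
#'
#' `no_data` when the period holds zero valid readings; `alerts` when any
#' alert-role rule (generic or personalized) triggers; otherwise
#' `no_alerts`. Wear-role rules annotate but never promote a patient to the
#' alerts tab.
#'
#' @inheritParams evaluate_flags
#' @return One of `"no_data"`, `"alerts"`, `"no_alerts"`.
#' @export
patient_status <- function(series, period, rules, base_spec = baseline_spec()) {
  review <- compute_period_metrics(series, period)
  if (review$n_valid == 0L) return("no_data")
  flags <- evaluate_flags(series, period, rules, base_spec)
  if (any(flags$triggered & flags$role == "alert")) "alerts" else "no_alerts"
}
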