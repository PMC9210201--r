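#' Per-patient-week metric table
#'
#' The longitudinal evaluation unit: every patient's series is first passed
#' through the valid-day filter, then partitioned into Sunday-aligned weeks
#' (a week is eligible when it contains at least one included day). For each
#' eligible patient-week the whole-day consensus metrics are computed,
#' together with the baseline-window values of mean glucose and TIR (the
#' configured number of weeks immediately preceding; `NA` when the baseline
#' window holds no included readings).
#'
#' @param cohort A [cgm_cohort()].
#' @param config A [tool_config()] (the `simulation` preset is the usual
#'   choice here).
#' @return A tibble with one row per eligible patient-week: `patient_id`,
#'   `week_start`, the metric columns, `mean_glucose_base`, `tir_pct_base`,
#'   and `n_weeks_patient` (the patient's total eligible weeks).
#' @export
patient_week_metrics <- function(cohort, config = tool_config("simulation")) {
  purrr::map_dfr(cohort, function(series) {
    filtered <- filter_valid_days(series, config$valid_day_fraction)
    if (nrow(filtered) == 0L) return(NULL)
    days <- unique(lubridate::as_date(filtered$timestamp))
    week_starts <- sort(unique(days - (lubridate::wday(days) - 1L) %% 7L))
    rows <- purrr::map_dfr(week_starts, function(ws) {
      period <- new_review_period(ws, ws + 7L, config$period_mode)
      m <- compute_period_metrics(filtered, period,
                                  min_day_fraction = config$valid_day_fraction)
      base <- compute_baseline_window(filtered, period, config$base_spec)
      dplyr::bind_cols(
        tibble(patient_id = series_patient_id(series), week_start = ws),
        m,
        tibble(mean_glucose_base = base$mean_glucose %||% NA_real_,
               tir_pct_base = base$tir_pct %||% NA_real_)
      )
    })
    rows$n_weeks_patient <- nrow(rows)
    rows
  })
}

# Baseline metrics over the window immediately preceding `period`, with no
# minimum-history gate (eligibility is handled at the patient level in the
# longitudinal evaluation).
compute_baseline_window <- function(series, period, spec) {
  base_period <- new_review_period(period$start - spec$n_weeks * 7L * 86400,
                                   period$start, "baseline")
  m <- compute_period_metrics(series, base_period)
  if (m$n_valid == 0L) return(NULL)
  m
}

#' Cohort summary statistics
#'
#' Descriptive statistics for one data set after valid-day filtering:
#' patient, day and week counts, mean days active per week, and
#' cross-patient-week mean (SD) of mean glucose, TIR, hypoglycemia and
#' extreme hypoglycemia.
#'
#' @inheritParams patient_week_metrics
#' @return A one-row tibble.
#' @export
summarize_cohort <- function(cohort, config = tool_config("simulation")) {
  if (length(cohort) == 0L) abort("empty cohort: nothing to summarize")
  pw <- patient_week_metrics(cohort, config)
  if (nrow(pw) == 0L) abort("no patient-weeks survive the valid-day filter")
  sd0 <- function(x) if (length(x) < 2L) 0 else stats::sd(x)
  tibble(
    n_patients = length(unique(pw$patient_id)),
    n_cgm_days = sum(pw$days_active),
    n_cgm_weeks = nrow(pw),
    days_active_mean = mean(pw$days_active),
    mg_mean = mean(pw$mean_glucose), mg_sd = sd0(pw$mean_glucose),
    tir_mean = mean(pw$tir_pct), tir_sd = sd0(pw$tir_pct),
    hyp_mean = mean(pw$hyp_pct), hyp_sd = sd0(pw$hyp_pct),
    ehyp_mean = mean(pw$ehyp_pct), ehyp_sd = sd0(pw$ehyp_pct)
  )
}

evaluate_week_flags <- function(row, rules, personalized_eligible) {
  gen <- evaluate_generic_flags(row, rules)
  per <- if (personalized_eligible && !is.na(row$mean_glucose_base)) {
    baseline <- tibble(mean_glucose = row$mean_glucose_base,
                       tir_pct = row$tir_pct_base)
    evaluate_personalized_flags(row, baseline, rules)
  } else {
    empty_flag_set()
  }
  dplyr::bind_rows(gen, per)
}

#' Weekly flag rates across a cohort
#'
#' For every eligible patient-week, generic flags are evaluated; for
#' patients with at least `min_history_weeks` (default 4) eligible weeks of
#' data, personalized flags are evaluated against the baseline window.
#' Per-patient rates are flags divided by that patient's evaluable weeks for
#' the rule; cohort rates pool flags over pooled weeks.
#'
#' @inheritParams patient_week_metrics
#' @return A list with `per_patient` (patient x rule rates), `summary`
#'   (per rule: pooled totals, pooled rate, cross-patient median, IQR and
#'   SD), `n_patients`, and `n_eligible` (patients meeting the
#'   personalized-history requirement).
#' @export
weekly_flag_rates <- function(cohort, config = tool_config("simulation")) {
  pw <- patient_week_metrics(cohort, config)
  rules <- config$rules
  min_hist <- config$base_spec$min_history_weeks
  if (nrow(pw) == 0L) {
    return(list(per_patient = tibble(), summary = tibble(),
                n_patients = 0L, n_eligible = 0L))
  }
  pw$eligible_personalized <- pw$n_weeks_patient >= min_hist
  flags <- purrr::map_dfr(seq_len(nrow(pw)), function(i) {
    row <- pw[i, ]
    f <- evaluate_week_flags(row, rules, row$eligible_personalized)
    f$patient_id <- row$patient_id
    f$week_start <- row$week_start
    f
  })
  per_patient <- flags %>%
    dplyr::group_by(.data$patient_id, .data$rule_id, .data$metric,
                    .data$kind) %>%
    dplyr::summarise(n_flags = sum(.data$triggered),
                     n_weeks = dplyr::n(),
                     rate = .data$n_flags / .data$n_weeks,
                     .groups = "drop")
  summary <- per_patient %>%
    dplyr::group_by(.data$rule_id, .data$metric, .data$kind) %>%
    dplyr::summarise(
      total_flags = sum(.data$n_flags),
      total_weeks = sum(.data$n_weeks),
      pooled_rate = .data$total_flags / .data$total_weeks,
      rate_median = stats::median(.data$rate),
      rate_q1 = unname(stats::quantile(.data$rate, 0.25)),
      rate_q3 = unname(stats::quantile(.data$rate, 0.75)),
      rate_sd = if (dplyr::n() < 2L) 0 else stats::sd(.data$rate),
      n_patients = dplyr::n(),
      .groups = "drop"
    )
  list(per_patient = per_patient, summary = summary,
       n_patients = length(unique(pw$patient_id)),
       n_eligible = length(unique(pw$patient_id[pw$eligible_personalized])))
}

#' Fraction of patients flagged every week
#'
#' Among patients with at least the personalized-history minimum of
#' eligible weeks, the fraction for whom *every* eligible week raised at
#' least one mean-glucose or TIR flag of the given kind.
#'
#' @inheritParams patient_week_metrics
#' @param kind `"generic"` or `"personalized"`.
#' @return A list with `fraction`, `n_flagged_every_week` and `n_eligible`.
#' @export
every_week_flagged_fraction <- function(cohort,
                                        config = tool_config("simulation"),
                                        kind = c("generic", "personalized")) {
  kind <- match.arg(kind)
  pw <- patient_week_metrics(cohort, config)
  min_hist <- config$base_spec$min_history_weeks
  pw <- pw[pw$n_weeks_patient >= min_hist, , drop = FALSE]
  if (nrow(pw) == 0L) {
    return(list(fraction = NA_real_, n_flagged_every_week = 0L,
                n_eligible = 0L))
  }
  rules <- Filter(function(r) {
    r$kind == kind && r$metric %in% c("mean_glucose", "tir_pct")
  }, config$rules)
  week_hit <- vapply(seq_len(nrow(pw)), function(i) {
    f <- evaluate_week_flags(pw[i, ], rules, personalized_eligible = TRUE)
    any(f$triggered)
  }, logical(1))
  per_patient <- tapply(week_hit, pw$patient_id, all)
  list(fraction = mean(per_patient),
       n_flagged_every_week = sum(per_patient),
       n_eligible = length(per_patient))
}

#' Paired two-tailed t test on per-patient flag rates
#'
#' The classical paired t test comparing, patient by patient, the rate of
#' generic flags with the rate of personalized flags. Degenerate inputs
#' (fewer than two pairs, or zero variance of the differences, including
#' identical vectors) return status `"undefined"` rather than a spurious
#' statistic.
#'
#' @param generic,personalized Paired numeric vectors of per-patient rates.
#' @return A list with `status` (`"ok"` or `"undefined"`), and for `"ok"`:
#'   `t`, `df`, `p_value`, `mean_diff`.
#' @export
paired_flag_rate_test <- function(generic, personalized) {
  stopifnot(length(generic) == length(personalized))
  d <- generic - personalized
  if (length(d) < 2L || isTRUE(all.equal(stats::sd(d), 0)) ||
      stats::sd(d) == 0) {
    return(list(status = "undefined", t = NA_real_, df = NA_real_,
                p_value = NA_real_, mean_diff = mean(d)))
  }
  ht <- stats::t.test(generic, personalized, paired = TRUE,
                      alternative = "two.sided")
  list(status = "ok", t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, mean_diff = unname(ht$estimate))
}

#' Reconstruct integer counts from printed percentages
#'
#' Published screening tables often print only rounded percentages and the
#' population size; the underlying integer counts are recovered as
#' `round(pct * n / 100)`, from which derived rates (sensitivity,
#' specificity, ...) can be recomputed exactly.
#'
#' @param pct Percentages (0--100).
#' @param n Population size.
#' @return Integer counts.
#' @export
#' @examples
#' counts_from_percent(c(29, 2), 56) # 16, 1
counts_from_percent <- function(pct, n) {
  as.integer(round(pct * n / 100))
}

#' Confusion-matrix summary of flagging against reference labels
#'
#' Cross-tabulates per patient-review flag outcomes against reference
#' appropriateness labels. Reviews labelled `insufficient_data` are
#' excluded from the 2x2 table but counted. Sensitivity, specificity,
#' positive and negative predictive value are reported in percent (`NA`
#' when a denominator is zero); the reduction in patients reviewed is the
#' unflagged fraction of the total population.
#'
#' @param flagged Logical vector: was the patient flagged for review.
#' @param label Character vector in `{appropriate, not_appropriate,
#'   insufficient_data}`, same length and order as `flagged`.
#' @param review Optional grouping vector (e.g. review week); when given,
#'   the summary has one row per review plus a pooled row.
#' @return A tibble with counts `tp`, `tn`, `fp`, `fn`, `insufficient`,
#'   `n`, and percentage columns `sensitivity`, `specificity`, `ppv`,
#'   `npv`, `reduction`.
#' @export
confusion_metrics <- function(flagged, label, review = NULL) {
  stopifnot(length(flagged) == length(label))
  ok <- label %in% c("appropriate", "not_appropriate", "insufficient_data")
  if (!all(ok)) abort("labels must be appropriate / not_appropriate / insufficient_data")
  if (is.null(review)) review <- rep("all", length(flagged))
  stopifnot(length(review) == length(flagged))
  df <- tibble(review = as.character(review), flagged = flagged,
               label = label)
  one <- function(d, name) {
    use <- d$label != "insufficient_data"
    tp <- sum(use & d$flagged & d$label == "appropriate")
    fn <- sum(use & !d$flagged & d$label == "appropriate")
    fp <- sum(use & d$flagged & d$label == "not_appropriate")
    tn <- sum(use & !d$flagged & d$label == "not_appropriate")
    pct <- function(num, den) if (den == 0L) NA_real_ else 100 * num / den
    tibble(review = name, n = nrow(d), tp = tp, tn = tn, fp = fp, fn = fn,
           insufficient = sum(!use),
           sensitivity = pct(tp, tp + fn), specificity = pct(tn, tn + fp),
           ppv = pct(tp, tp + fp), npv = pct(tn, tn + fn),
           reduction = pct(sum(!d$flagged), nrow(d)))
  }
  per <- purrr::map_dfr(unique(df$review), function(nm) {
    one(df[df$review == nm, ], nm)
  })
  if (length(unique(df$review)) > 1L) {
    per <- dplyr::bind_rows(per, one(df, "pooled"))
  }
  per
}

#' Distribution plot of per-patient flag rates
#'
#' Box plots of the per-patient weekly flag rates by rule, separating
#' generic from personalized rules — the visual companion to
#' [weekly_flag_rates()].
#'
#' @param rates The result of [weekly_flag_rates()].
#' @return A ggplot object.
#' @export
plot_flag_rate_distribution <- function(rates) {
  df <- rates$per_patient
  df <- df[df$metric %in% c("mean_glucose", "tir_pct"), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$rate,
                                   fill = .data$kind)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::scale_x_discrete(labels = c(mean_glucose = "Mean glucose",
                                         tir_pct = "TIR")) +
    ggplot2::labs(x = NULL, y = "Flags per patient per week",
                  fill = "Flag kind") +
    ggplot2::theme_minimal()
}
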