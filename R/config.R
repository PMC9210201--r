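#' Tool configuration
#'
#' One declarative object binds the modules together: the active rule set,
#' the review-period convention, the baseline specification, the valid-day
#' rule and output options. The two [rule_preset()]s carry matching
#' defaults: the `clinic` preset reviews the Monday-to-Sunday week ending
#' before the review date against a 4-week baseline; the `simulation`
#' preset uses Sunday-starting weeks against the previous single week.
#'
#' @param preset Name of a built-in rule preset, or `NULL` when `rules`
#'   are given explicitly.
#' @param rules Explicit list of [flag_rule()]s overriding the preset.
#' @param period_mode Review-period convention (see
#'   [resolve_review_period()]); `NULL` takes the preset default.
#' @param baseline_n_weeks Baseline window length in weeks; `NULL` takes
#'   the preset default (clinic 4, simulation 1).
#' @param min_history_weeks Minimum weeks of history for personalized
#'   flags (default 4).
#' @param valid_day_fraction Valid-day inclusion threshold (default 0.70).
#' @param min_valid_days Minimum valid days in a period before a patient is
#'   treated as having sufficient data in confusion summaries (default 1).
#' @param segments Day segments to report (always includes `whole_day`).
#' @param no_data_unreviewed Count no-data patients as "not reviewed" in
#'   [reviewed_reduction()] (default `TRUE`).
#' @param output_dir Directory for rendered reports.
#' @return A `tool_config` list.
#' @export
tool_config <- function(preset = "clinic", rules = NULL, period_mode = NULL,
                        baseline_n_weeks = NULL, min_history_weeks = 4L,
                        valid_day_fraction = 0.70, min_valid_days = 1L,
                        segments = "whole_day", no_data_unreviewed = TRUE,
                        output_dir = ".") {
  if (is.null(rules)) {
    if (is.null(preset)) abort("either a preset name or explicit rules required")
    rules <- rule_preset(preset)
  }
  if (is.null(period_mode)) {
    period_mode <- if (identical(preset, "simulation")) {
      "week_starting_sunday"
    } else {
      "week_ending_sunday"
    }
  }
  period_mode <- match.arg(period_mode, c("week_ending_sunday",
                                          "trailing_7_days",
                                          "week_starting_sunday"))
  if (is.null(baseline_n_weeks)) {
    baseline_n_weeks <- if (identical(preset, "simulation")) 1L else 4L
  }
  stopifnot(valid_day_fraction >= 0, valid_day_fraction <= 1)
  segments <- union("whole_day", match.arg(segments, DAY_SEGMENTS,
                                           several.ok = TRUE))
  structure(list(
    preset = preset, rules = rules, period_mode = period_mode,
    base_spec = baseline_spec(baseline_n_weeks, min_history_weeks),
    valid_day_fraction = valid_day_fraction,
    min_valid_days = as.integer(min_valid_days),
    segments = segments, no_data_unreviewed = no_data_unreviewed,
    output_dir = output_dir
  ), class = "tool_config")
}

#' Read a tool configuration from a YAML file
#'
#' Recognized keys mirror the [tool_config()] arguments (`preset`,
#' `period_mode`, `baseline_n_weeks`, `min_history_weeks`,
#' `valid_day_fraction`, `min_valid_days`, `segments`,
#' `no_data_unreviewed`, `output_dir`), plus an optional `rules` list whose
#' entries carry `metric`, `kind`, `comparator`, `threshold` and optional
#' `role`. Unspecified keys fall back to the preset defaults.
#'
#' @param path Path to a YAML file.
#' @return A `tool_config`.
#' @export
read_tool_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  y <- yaml::read_yaml(path)
  rules <- NULL
  if (!is.null(y$rules)) {
    rules <- lapply(y$rules, function(r) {
      flag_rule(r$metric, r$kind %||% "generic", r$comparator,
                r$threshold, r$role %||% "alert")
    })
  }
  tool_config(
    preset = y$preset %||% (if (is.null(rules)) "clinic" else NULL),
    rules = rules,
    period_mode = y$period_mode,
    baseline_n_weeks = y$baseline_n_weeks,
    min_history_weeks = y$min_history_weeks %||% 4L,
    valid_day_fraction = y$valid_day_fraction %||% 0.70,
    min_valid_days = y$min_valid_days %||% 1L,
    segments = y$segments %||% "whole_day",
    no_data_unreviewed = y$no_data_unreviewed %||% TRUE,
    output_dir = y$output_dir %||% "."
  )
}
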