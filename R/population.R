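#' Build the per-review population triage report
#'
#' Computes metrics, flags and a triage status for every patient in the
#' cohort over the review period implied by `review_date` and the
#' configuration, and partitions the rows into the four triage tabs: all
#' patients, patients with alerts, patients with no data in the period, and
#' patients with data but no alerts. Rows are sorted alerts-first, then by
#' descending mean glucose, ties by patient id.
#'
#' @param cohort A [cgm_cohort()].
#' @param review_date Date of the review.
#' @param config A [tool_config()].
#' @return A `population_report` list with `period`, `rows` (a tibble with
#'   one row per patient: metrics columns, `status`, `n_flags`, `flags`
#'   list-column, and per-segment metric columns when configured), and
#'   `tabs` (named list of patient-id character vectors).
#' @export
build_population_report <- function(cohort, review_date,
                                    config = tool_config()) {
  period <- resolve_review_period(review_date, config$period_mode)
  rows <- purrr::map_dfr(cohort, function(series) {
    report_row(series, period, config)
  })
  if (nrow(rows) == 0L) {
    rows <- tibble(patient_id = character(), status = character())
  } else {
    mg <- rows$mean_glucose
    mg[is.na(mg)] <- -Inf
    ord <- order(rows$status != "alerts", -mg, rows$patient_id,
                 method = "radix")
    rows <- rows[ord, ]
  }
  tabs <- list(
    all = rows$patient_id,
    alerts = rows$patient_id[rows$status == "alerts"],
    no_data = rows$patient_id[rows$status == "no_data"],
    no_alerts = rows$patient_id[rows$status == "no_alerts"]
  )
  structure(list(period = period, rows = rows, tabs = tabs,
                 config = config, review_date = as_naive_date(review_date)),
            class = "population_report")
}

report_row <- function(series, period, config) {
  metrics <- compute_period_metrics(series, period,
                                    min_day_fraction = config$valid_day_fraction)
  base <- compute_baseline(series, period, config$base_spec)
  flags <- dplyr::bind_rows(
    evaluate_generic_flags(metrics, config$rules),
    evaluate_personalized_flags(metrics, base, config$rules)
  )
  status <- if (metrics$n_valid == 0L) {
    "no_data"
  } else if (any(flags$triggered & flags$role == "alert")) {
    "alerts"
  } else {
    "no_alerts"
  }
  row <- dplyr::bind_cols(
    tibble(patient_id = series_patient_id(series)),
    metrics,
    tibble(status = status,
           n_flags = sum(flags$triggered),
           wear_attention = any(flags$triggered & flags$role == "wear"),
           flags = list(flags))
  )
  extra <- setdiff(config$segments, "whole_day")
  for (seg in extra) {
    m <- compute_period_metrics(series, period, seg,
                                min_day_fraction = config$valid_day_fraction)
    keep <- c("mean_glucose", "tir_pct", "hyp_pct", "ehyp_pct", "act_pct")
    names(m) <- paste0(names(m), "_", seg)
    row <- dplyr::bind_cols(row, m[paste0(keep, "_", seg)])
  }
  row
}

#' @export
print.population_report <- function(x, ...) {
  cat(sprintf("<population_report> [%s, %s): %d patients (%d alerts, %d no data, %d no alerts)\n",
              fmt_ts(x$period$start), fmt_ts(x$period$end),
              length(x$tabs$all), length(x$tabs$alerts),
              length(x$tabs$no_data), length(x$tabs$no_alerts)))
  invisible(x)
}

#' Reduction in the number of patients reviewed
#'
#' The workload saving of flag-based triage: the number of patients *not*
#' flagged for review, as a percentage of the total population. Patients
#' with no data count as unreviewed by default (configurable through
#' [tool_config()]). Given a list of reports, counts are pooled across
#' reviews before dividing.
#'
#' Can also be called directly on counts: `reviewed_reduction(182, 427)`
#' returns `100 * 182 / 427`.
#'
#' @param x A `population_report`, a list of them, or an unflagged count.
#' @param total Total population size (count form only).
#' @return A percentage.
#' @export
#' @examples
#' reviewed_reduction(182, 427) # 42.62...
reviewed_reduction <- function(x, total = NULL) {
  UseMethod("reviewed_reduction")
}

#' @export
reviewed_reduction.numeric <- function(x, total = NULL) {
  stopifnot(!is.null(total), total > 0)
  100 * x / total
}

report_reduction_counts <- function(report) {
  n_total <- length(report$tabs$all)
  unflagged <- length(report$tabs$no_alerts) +
    if (report$config$no_data_unreviewed) length(report$tabs$no_data) else 0L
  c(unflagged = unflagged, total = n_total)
}

#' @export
reviewed_reduction.population_report <- function(x, total = NULL) {
  counts <- report_reduction_counts(x)
  if (counts[["total"]] == 0L) abort("empty report: reduction undefined")
  100 * counts[["unflagged"]] / counts[["total"]]
}

#' @export
reviewed_reduction.list <- function(x, total = NULL) {
  counts <- rowSums(vapply(x, report_reduction_counts, double(2)))
  if (counts[["total"]] == 0L) abort("empty reports: reduction undefined")
  100 * counts[["unflagged"]] / counts[["total"]]
}

report_table <- function(report) {
  rows <- report$rows
  if (nrow(rows) == 0L) {
    return(tibble(patient_id = character(), tab = character()))
  }
  rows$tab <- rows$status
  rows$flags_triggered <- vapply(rows$flags, function(f) {
    paste(f$rule_id[f$triggered], collapse = ";")
  }, character(1))
  rows$flags <- NULL
  dplyr::relocate(rows, "patient_id", "tab")
}

#' Render a population report to CSV or a static HTML page
#'
#' The CSV form has one row per patient with metric columns, the triage tab
#' and a semicolon-separated list of triggered flags. The HTML form is a
#' static four-tab page in which only metric cells that triggered a flag
#' carry the `flagged` highlight class.
#'
#' @param report A `population_report`.
#' @param format `"csv"` or `"html"`.
#' @param path Output file path; defaults to
#'   `report-<review date>.<format>` under the configured output directory.
#' @return The output path, invisibly.
#' @export
render_report <- function(report, format = c("csv", "html"), path = NULL) {
  format <- rlang::arg_match(format)
  if (is.null(path)) {
    dir <- report$config$output_dir
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    path <- file.path(dir, sprintf("report-%s.%s", report$review_date, format))
  }
  if (format == "csv") {
    readr::write_csv(report_table(report), path, progress = FALSE)
  } else {
    writeLines(render_report_html(report), path)
  }
  invisible(path)
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

render_report_html <- function(report) {
  metric_cols <- c(act_pct = "ACT %", mean_glucose = "Mean glucose",
                   tir_pct = "TIR %", hyp_pct = "Hyp %", ehyp_pct = "eHyp %")
  fmt_cell <- function(value, flagged) {
    shown <- if (is.na(value)) "&mdash;" else sprintf("%.1f", value)
    cls <- if (isTRUE(flagged)) " class=\"flagged\"" else ""
    sprintf("<td%s>%s</td>", cls, shown)
  }
  row_html <- function(row) {
    flags <- row$flags[[1L]]
    cells <- vapply(names(metric_cols), function(m) {
      fmt_cell(row[[m]], any(flags$triggered & flags$metric == m))
    }, character(1))
    sprintf("<tr><td>%s</td>%s<td>%d</td></tr>",
            html_escape(row$patient_id), paste(cells, collapse = ""),
            row$n_flags)
  }
  tab_html <- function(tab_name, ids) {
    rows <- report$rows[report$rows$patient_id %in% ids, , drop = FALSE]
    body <- if (nrow(rows) == 0L) "" else {
      paste(vapply(seq_len(nrow(rows)),
                   function(i) row_html(rows[i, ]), character(1)),
            collapse = "\n")
    }
    sprintf(paste0(
      "<section id=\"%s\"><h2>%s (%d)</h2>\n",
      "<table><thead><tr><th>Patient</th>%s<th>Flags</th></tr></thead>\n",
      "<tbody>\n%s\n</tbody></table></section>"),
      tab_name, gsub("_", " ", tab_name), length(ids),
      paste(sprintf("<th>%s</th>", metric_cols), collapse = ""), body)
  }
  c("<!DOCTYPE html>",
    "<html><head><meta charset=\"utf-8\">",
    sprintf("<title>CGM population review %s</title>", report$review_date),
    "<style>",
    "table{border-collapse:collapse}td,th{border:1px solid #999;padding:2px 6px}",
    ".flagged{background:#f8d7da;font-weight:bold}",
    "</style></head><body>",
    sprintf("<h1>Review period [%s, %s)</h1>",
            fmt_ts(report$period$start), fmt_ts(report$period$end)),
    vapply(names(report$tabs), function(tn) tab_html(tn, report$tabs[[tn]]),
           character(1)),
    "</body></html>")
}
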