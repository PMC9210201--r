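sim_cfg <- tool_config("simulation")

test_that("cohort summary counts days and weeks after the valid-day filter", {
  s <- make_series(100, n_days = 7)
  out <- summarize_cohort(cgm_cohort(list(s)), sim_cfg)
  expect_identical(out$n_patients, 1L)
  expect_identical(out$n_cgm_days, 7L)
  expect_identical(out$n_cgm_weeks, 1L)
  expect_equal(out$mg_mean, 100)
  expect_equal(out$mg_sd, 0)
  expect_equal(out$tir_mean, 100)

  # two identical patients: per-week means unchanged, counts doubled
  s2 <- make_series(100, n_days = 7, id = "p2")
  out2 <- summarize_cohort(cgm_cohort(list(s, s2)), sim_cfg)
  expect_identical(out2$n_patients, 2L)
  expect_identical(out2$n_cgm_weeks, 2L)
  expect_equal(out2$mg_mean, out$mg_mean)

  expect_error(summarize_cohort(cgm_cohort(list()), sim_cfg), "empty cohort")
})

test_that("cohort summary equals a brute-force per-patient-week recomputation", {
  co <- generate_cohort(6, n_weeks = 4, cohort_mean = 165, cohort_sd = 30,
                        wear_prob = 0.85, seed = 17)
  out <- summarize_cohort(co, sim_cfg)
  # oracle: census days, then scan each Sunday-aligned week independently
  mgs <- c(); tirs <- c(); weeks <- 0L; days <- 0L
  for (s in co) {
    census <- oracle_day_census(s)
    good_days <- as.Date(names(census))[census / 288 >= 0.70]
    days <- days + length(good_days)
    kept <- s[as.Date(format(s$timestamp, "%Y-%m-%d")) %in% good_days, ]
    if (length(good_days) == 0L) next
    ws <- sort(unique(good_days - (as.integer(format(good_days, "%w")))))
    for (w in as.list(ws)) {
      o <- oracle_scan(kept, t0(w), t0(w + 7), c(0L, 1440L), 5L)
      if (o$n_valid > 0L) {
        weeks <- weeks + 1L
        mgs <- c(mgs, o$mean_glucose)
        tirs <- c(tirs, o$tir_pct)
      }
    }
  }
  expect_identical(out$n_cgm_days, days)
  expect_identical(out$n_cgm_weeks, weeks)
  expect_equal(out$mg_mean, mean(mgs), tolerance = 1e-12)
  expect_equal(out$mg_sd, sd(mgs), tolerance = 1e-12)
  expect_equal(out$tir_mean, mean(tirs), tolerance = 1e-12)
})

test_that("stationary in-range cohorts raise no flags", {
  co <- cgm_cohort(list(make_series(100, n_days = 28, id = "a"),
                        make_series(110, n_days = 28, id = "b")))
  rates <- weekly_flag_rates(co, sim_cfg)
  expect_true(all(rates$summary$pooled_rate == 0))
})

test_that("uniformly high mean glucose forces generic rate 1 and personalized 0", {
  co <- cgm_cohort(list(make_series(200, n_days = 35, id = "a"),
                        make_series(200, n_days = 35, id = "b")))
  rates <- weekly_flag_rates(co, sim_cfg)
  s <- rates$summary
  expect_equal(s$pooled_rate[s$rule_id == "generic_mean_glucose"], 1)
  expect_equal(s$pooled_rate[s$rule_id == "personalized_mean_glucose"], 0)
})

test_that("personalized denominators never exceed generic denominators", {
  co <- generate_cohort(8, n_weeks = 5, wear_prob = 0.75, seed = 9)
  rates <- weekly_flag_rates(co, sim_cfg)
  s <- rates$summary
  for (metric in c("mean_glucose", "tir_pct")) {
    gen <- s$total_weeks[s$rule_id == paste0("generic_", metric)]
    per <- s$total_weeks[s$rule_id == paste0("personalized_", metric)]
    if (length(per) == 1L) expect_lte(per, gen)
  }
})

test_that("every-week-flagged fraction hits its forced extremes", {
  hot <- cgm_cohort(list(make_series(200, n_days = 35, id = "a")))
  ew <- every_week_flagged_fraction(hot, sim_cfg, "generic")
  expect_equal(ew$fraction, 1.0)
  expect_identical(ew$n_eligible, 1L)

  cool <- cgm_cohort(list(make_series(100, n_days = 35, id = "a")))
  expect_equal(every_week_flagged_fraction(cool, sim_cfg, "generic")$fraction, 0)
  expect_equal(every_week_flagged_fraction(cool, sim_cfg,
                                           "personalized")$fraction, 0)

  # mixed seeded cohort equals a brute-force all-weeks scan
  co <- generate_cohort(10, n_weeks = 5, cohort_mean = 175, cohort_sd = 30,
                        seed = 27)
  ew2 <- every_week_flagged_fraction(co, sim_cfg, "generic")
  pw <- patient_week_metrics(co, sim_cfg)
  pw <- pw[pw$n_weeks_patient >= 4, ]
  hit <- pw$mean_glucose > 170 | pw$tir_pct < 60
  brute <- tapply(hit, pw$patient_id, all)
  expect_equal(ew2$fraction, mean(brute))
  expect_equal(ew2$n_flagged_every_week, sum(brute))
})

test_that("paired t test matches the textbook closed form and guards degeneracy", {
  g <- c(0.5, 0.7, 0.9, 0.4)
  p <- c(0.2, 0.1, 0.3, 0.2)
  out <- paired_flag_rate_test(g, p)
  d <- g - p
  t_hand <- mean(d) / (sd(d) / sqrt(length(d)))
  p_hand <- 2 * pt(-abs(t_hand), df = length(d) - 1)
  expect_identical(out$status, "ok")
  expect_equal(out$t, t_hand, tolerance = 1e-9)
  expect_equal(out$df, 3)
  expect_equal(out$p_value, p_hand, tolerance = 1e-9)

  expect_identical(paired_flag_rate_test(g, g)$status, "undefined")
  expect_identical(paired_flag_rate_test(g, g - 0.1)$status, "undefined")
  expect_identical(paired_flag_rate_test(1, 2)$status, "undefined")
})

test_that("count reconstruction from printed percentages recovers exact rates", {
  expect_identical(counts_from_percent(c(29, 2), 56), c(16L, 1L))
  # week-1-style reconstruction: sensitivity 16/17 rounds to 94%
  tp <- counts_from_percent(29, 56); fn <- counts_from_percent(2, 56)
  expect_equal(round(100 * tp / (tp + fn)), 94)
  # equal TN/FP percentages force 50% specificity
  tn <- counts_from_percent(23, 56); fp <- counts_from_percent(23, 56)
  expect_equal(round(100 * tn / (tn + fp)), 50)
})

test_that("confusion summary cross-tabulates and excludes insufficient data", {
  flagged <- c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)
  label <- c("appropriate", "not_appropriate", "not_appropriate",
             "appropriate", "insufficient_data", "insufficient_data")
  out <- confusion_metrics(flagged, label)
  expect_identical(out$tp, 1L); expect_identical(out$fp, 1L)
  expect_identical(out$tn, 1L); expect_identical(out$fn, 1L)
  expect_identical(out$insufficient, 2L)
  expect_identical(out$tp + out$tn + out$fp + out$fn + out$insufficient,
                   out$n)
  expect_equal(out$sensitivity, 50)
  expect_equal(out$reduction, 50)

  # FN = 0 with TP > 0 forces sensitivity 100
  out2 <- confusion_metrics(c(TRUE, FALSE), c("appropriate", "not_appropriate"))
  expect_equal(out2$sensitivity, 100)
  expect_equal(out2$specificity, 100)

  # zero denominators are undefined, not zero
  out3 <- confusion_metrics(c(TRUE, TRUE), c("appropriate", "appropriate"))
  expect_true(is.na(out3$specificity))

  expect_error(confusion_metrics(TRUE, c("appropriate", "appropriate")))
  expect_error(confusion_metrics(TRUE, "maybe"), "labels must be")

  # grouped form adds a pooled row
  out4 <- confusion_metrics(flagged, label, review = c(1, 1, 1, 2, 2, 2))
  expect_identical(nrow(out4), 3L)
  expect_identical(out4$review[3L], "pooled")
  expect_identical(out4$n[3L], 6L)
})

test_that("rates are invariant to patient relabeling", {
  co <- generate_cohort(5, n_weeks = 5, seed = 77)
  relabeled <- cgm_cohort(lapply(seq_along(co), function(i) {
    s <- co[[i]]
    cgm_series(sprintf("z%02d", i), s$timestamp, s$glucose,
               interval_min = series_interval(s))
  }))
  r1 <- weekly_flag_rates(co, sim_cfg)$summary
  r2 <- weekly_flag_rates(relabeled, sim_cfg)$summary
  expect_equal(r1$pooled_rate, r2$pooled_rate)
  expect_equal(r1$rate_sd, r2$rate_sd)
})
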