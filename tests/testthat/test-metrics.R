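test_that("week_ending_sunday matches a day-by-day calendar oracle for every weekday", {
  # one review date of each weekday
  for (d in as.list(as.Date("2020-02-03") + 0:6)) {
    p <- resolve_review_period(d, "week_ending_sunday")
    last_sun <- oracle_last_sunday_before(d)
    expect_equal(as.Date(p$end) - 1, last_sun, info = format(d))
    expect_equal(as.Date(p$start), last_sun - 6)
    expect_identical(p$days, 7L)
  }
  # reviewing on a Monday: the period ends the previous day at 24:00
  mon <- as.Date("2020-02-10")
  p <- resolve_review_period(mon, "week_ending_sunday")
  expect_equal(as.Date(p$end), mon)
  # reviewing on a Sunday: that Sunday is excluded, period ends a week back
  sun <- as.Date("2020-02-09")
  p <- resolve_review_period(sun, "week_ending_sunday")
  expect_equal(as.Date(p$end) - 1, sun - 7)
})

test_that("trailing and Sunday-start conventions resolve as defined", {
  d <- as.Date("2020-02-12") # a Wednesday
  p <- resolve_review_period(d, "trailing_7_days")
  expect_equal(as.Date(p$start), d - 7)
  expect_equal(as.Date(p$end), d)

  p <- resolve_review_period(d, "week_starting_sunday")
  expect_equal(format(as.Date(p$start), "%u"), "7") # starts a Sunday
  expect_true(as.Date(p$end) <= d)
  expect_true(as.Date(p$end) + 7 > d) # the *last* full week

  sun <- as.Date("2020-02-09")
  p <- resolve_review_period(sun, "week_starting_sunday")
  expect_equal(as.Date(p$start), sun - 7)
})

test_that("maximum possible readings follow the sampling arithmetic", {
  expect_identical(max_possible_readings(1, "whole_day", 5), 288L)
  expect_identical(max_possible_readings(1, "whole_day", 15), 96L)
  expect_identical(max_possible_readings(7, "nighttime", 5), 504L)
  expect_identical(max_possible_readings(7, "daytime", 15), 504L)
  expect_error(max_possible_readings(1, "whole_day", 7), "5 or 15")
})

test_that("constant full-week series yields the forced metric values", {
  s <- make_series(100, n_days = 7)
  p <- resolve_review_period(SUNDAY0 + 7, "week_starting_sunday")
  m <- compute_period_metrics(s, p)
  expect_identical(m$n_valid, 2016L)
  expect_equal(m$act_pct, 100)
  expect_equal(m$mean_glucose, 100)
  expect_equal(m$tir_pct, 100)
  expect_equal(m$hyp_pct, 0)
  expect_equal(m$ehyp_pct, 0)
  expect_identical(m$days_active, 7L)
})

test_that("empty window reports no-data markers, never zeros", {
  s <- make_series(100, n_days = 7)
  p <- resolve_review_period(SUNDAY0 + 70, "week_starting_sunday")
  m <- compute_period_metrics(s, p)
  expect_identical(m$n_valid, 0L)
  expect_equal(m$act_pct, 0)
  expect_true(is.na(m$mean_glucose))
  expect_true(is.na(m$tir_pct))
  expect_true(is.na(m$hyp_pct))
})

test_that("metrics equal an independent brute-force scan on seeded data", {
  set.seed(101)
  p <- resolve_review_period(SUNDAY0 + 7, "week_starting_sunday")
  for (rep in 1:3) {
    g <- exp(rnorm(2016, log(140), 0.35)) # spans all threshold classes
    g <- pmin(pmax(g, 41), 399)
    s <- make_series(g, n_days = 7)
    for (seg in names(segment_minutes)) {
      m <- compute_period_metrics(s, p, seg)
      o <- oracle_scan(s, p$start, p$end, segment_minutes[[seg]], 5L)
      expect_equal(m$n_valid, o$n_valid)
      for (f in c("act_pct", "mean_glucose", "tir_pct", "hyp_pct",
                  "ehyp_pct", "tar_pct")) {
        expect_equal(m[[f]], o[[f]], tolerance = 1e-12, info = seg)
      }
    }
  }
})

test_that("metric invariants hold on generated series", {
  for (seed in 1:5) {
    s <- generate_patient(patient_profile(seed = seed, n_weeks = 2,
                                          target_mean = 120 + 30 * seed))
    p <- resolve_review_period(SUNDAY0 + 7, "week_starting_sunday")
    m <- compute_period_metrics(s, p)
    if (m$n_valid > 0L) {
      expect_equal(m$tir_pct + m$hyp_pct + m$tar_pct, 100, tolerance = 1e-9)
      expect_lte(m$ehyp_pct, m$hyp_pct)
    }
    expect_gte(m$act_pct, 0)
    expect_lte(m$act_pct, 100)
    md <- compute_period_metrics(s, p, "daytime")
    mn <- compute_period_metrics(s, p, "nighttime")
    expect_identical(m$n_valid, md$n_valid + mn$n_valid)
  }
})

test_that("mean glucose is scale-equivariant and rate metrics permutation-invariant", {
  set.seed(7)
  g <- runif(288, 60, 250)
  s <- make_series(g, n_days = 1)
  p <- new_period_for_test(SUNDAY0, 1)
  m1 <- compute_period_metrics(s, p)
  s2 <- make_series(1.5 * g, n_days = 1)
  m2 <- compute_period_metrics(s2, p)
  expect_equal(m2$mean_glucose, 1.5 * m1$mean_glucose)

  s3 <- make_series(sample(g), n_days = 1)
  m3 <- compute_period_metrics(s3, p)
  expect_equal(m3$tir_pct, m1$tir_pct)
  expect_equal(m3$hyp_pct, m1$hyp_pct)
  expect_equal(m3$ehyp_pct, m1$ehyp_pct)
})

test_that("valid-day fraction is readings over possible slots", {
  s <- make_series(100, n_days = 1)
  expect_equal(valid_day_fraction(s, SUNDAY0), 1.0)
  s201 <- cgm_series("p1", t0() + (0:200) * 300, rep(100, 201))
  expect_equal(valid_day_fraction(s201, SUNDAY0), 201 / 288)
  expect_lt(valid_day_fraction(s201, SUNDAY0), 0.70)
  s202 <- cgm_series("p1", t0() + (0:201) * 300, rep(100, 202))
  expect_equal(valid_day_fraction(s202, SUNDAY0), 202 / 288)
  expect_gte(valid_day_fraction(s202, SUNDAY0), 0.70)
})

test_that("the valid-day filter removes exactly the under-covered days", {
  s <- make_series(100, n_days = 7)
  expect_equal(nrow(filter_valid_days(s)), nrow(s))

  # replace day 3 with 50% coverage
  keep <- !(lubridate::as_date(s$timestamp) == SUNDAY0 + 2 &
              seq_along(s$timestamp) %% 2 == 0)
  partial <- cgm_series("p1", s$timestamp[keep], s$glucose[keep],
                        interval_min = 5L)
  filtered <- filter_valid_days(partial)
  days_left <- unique(lubridate::as_date(filtered$timestamp))
  expect_false((SUNDAY0 + 2) %in% days_left)
  expect_length(days_left, 6L)

  # seeded dropout series: surviving days equal an independent census
  set.seed(13)
  s4 <- generate_patient(patient_profile(seed = 13, n_weeks = 4,
                                         wear_prob = 0.7))
  census <- oracle_day_census(s4)
  expected_days <- sum(census / 288 >= 0.70)
  got <- filter_valid_days(s4)
  expect_length(unique(lubridate::as_date(got$timestamp)), expected_days)
})
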