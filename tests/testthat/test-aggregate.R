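# Hierarchical temporal averaging and its completeness criteria.

test_that("daily averages follow the 12-hour completeness rule", {
  hr <- make_hourly_days(list("2015-03-01" = 24, "2015-03-02" = 12,
                              "2015-03-03" = 11),
                         list(50, 10 * (1:12), 30))
  d <- daily_average(hr)
  expect_equal(d$value[d$period_key == "2015-03-01"], 50)
  expect_equal(d$n_contributing[d$period_key == "2015-03-01"], 24)
  # exactly 12 hours: computed; mean of 10,20,...,120 is 65
  expect_equal(d$value[d$period_key == "2015-03-02"], 65)
  # 11 hours: missing
  expect_true(is.na(d$value[d$period_key == "2015-03-03"]))
})

test_that("duplicate site-hours are rejected", {
  hr <- make_hourly_days(list("2015-03-01" = 5), list(50))
  expect_error(daily_average(rbind(hr, hr[1, ])), "duplicate")
})

test_that("weekly averages follow the 3-day completeness rule", {
  # ISO week 2015-W10 is Mon 2015-03-02 .. Sun 2015-03-08
  hr3 <- make_hourly_days(list("2015-03-02" = 24, "2015-03-04" = 24,
                               "2015-03-06" = 24), list(30, 40, 50))
  w3 <- weekly_average(daily_average(hr3))
  expect_equal(w3$value[w3$period_key == "2015-W10"], 40)
  hr2 <- make_hourly_days(list("2015-03-02" = 24, "2015-03-04" = 24),
                          list(30, 40))
  w2 <- weekly_average(daily_average(hr2))
  expect_true(is.na(w2$value[w2$period_key == "2015-W10"]))
  # 4 days {10,20,30,60} -> 30; a day failing the hour rule cannot count
  hr4 <- make_hourly_days(list("2015-03-02" = 24, "2015-03-03" = 24,
                               "2015-03-04" = 24, "2015-03-05" = 24,
                               "2015-03-06" = 11),
                          list(10, 20, 30, 60, 999))
  w4 <- weekly_average(daily_average(hr4))
  expect_equal(w4$value[w4$period_key == "2015-W10"], 30)
  expect_equal(w4$n_contributing[w4$period_key == "2015-W10"], 4)
})

test_that("annual averages follow the 25%-of-weeks rule", {
  # build weekly tables directly: 13 of 52 weeks passes, 12 fails
  # ISO year 2016 has 52 weeks (2015 has 53, which would need 14)
  mk_weekly <- function(n_weeks, value = 35) {
    data.frame(site_id = "S1", pollutant = "NO2", period = "week",
               period_key = sprintf("2016-W%02d", seq_len(n_weeks)),
               value = value, n_contributing = 7,
               stringsAsFactors = FALSE)
  }
  a13 <- annual_average(mk_weekly(13))
  expect_equal(a13$value, 35)
  a12 <- annual_average(mk_weekly(12))
  expect_true(is.na(a12$value))
  # mean of 26 weeks at 20 and 26 at 60 is 40
  wk <- mk_weekly(52)
  wk$value <- rep(c(20, 60), each = 26)
  expect_equal(annual_average(wk)$value, 40)
})

test_that("the long-term mean averages available annual values only", {
  ann <- data.frame(site_id = "S1", pollutant = "NO2", period = "year",
                    period_key = as.character(2015:2020),
                    value = c(48, 44, 42, NA, 36, 30),
                    n_contributing = 52, stringsAsFactors = FALSE)
  ltm <- long_term_mean(ann, 2015:2020)
  expect_equal(ltm$value, 40)
  expect_equal(ltm$n_contributing, 5)
  one <- long_term_mean(ann[ann$period_key == "2016", ], 2016)
  expect_equal(one$value, 44)
  expect_error(long_term_mean(ann, integer(0)), "nonempty")
})

test_that("aggregation is idempotent on constant series", {
  set.seed(9)
  days <- as.character(seq(as.Date("2015-01-01"), as.Date("2015-12-31"),
                           by = "day"))
  hr <- make_hourly_days(setNames(as.list(rep(24, length(days))), days),
                         as.list(rep(42, length(days))))
  agg <- aggregate_concentrations(hr)
  expect_true(all(agg$daily$value == 42))
  expect_true(all(na.omit(agg$weekly$value) == 42))
  expect_equal(agg$annual$value[agg$annual$period_key == "2015"], 42)
  expect_equal(agg$ltm$value, 42)
})

test_that("tightening completeness thresholds never adds aggregates", {
  set.seed(21)
  days <- as.character(seq(as.Date("2015-01-01"), as.Date("2015-12-31"),
                           by = "day"))
  nh <- sample(0:24, length(days), replace = TRUE)
  keep <- nh > 0
  hr <- make_hourly_days(setNames(as.list(nh[keep]), days[keep]),
                         as.list(runif(sum(keep), 20, 60)))
  n_avail <- function(min_hours, min_days, min_frac) {
    agg <- aggregate_concentrations(hr, min_hours = min_hours,
                                    min_days = min_days,
                                    min_frac = min_frac)
    c(sum(!is.na(agg$daily$value)), sum(!is.na(agg$weekly$value)),
      sum(!is.na(agg$annual$value)))
  }
  loose <- n_avail(6, 2, 0.1)
  base <- n_avail(12, 3, 0.25)
  tight <- n_avail(18, 5, 0.5)
  expect_true(all(base <= loose))
  expect_true(all(tight <= base))
})

test_that("aggregation matches a brute-force calendar oracle", {
  # oracle: materialize the local calendar explicitly per day/week/year
  oracle <- function(hr, utc_offset = 8) {
    local <- hr$timestamp + utc_offset * 3600
    day <- as.Date(format(local, "%Y-%m-%d", tz = "UTC"))
    dmap <- split(hr$value, day)
    dval <- vapply(dmap, function(v) if (length(v) >= 12) mean(v)
                   else NA_real_, numeric(1))
    wk <- format(as.Date(names(dval)), "%G-W%V")
    wmap <- split(dval[!is.na(dval)], wk[!is.na(dval)])
    wval <- vapply(wmap, function(v) if (length(v) >= 3) mean(v)
                   else NA_real_, numeric(1))
    yr <- substr(names(wval), 1, 4)
    ymap <- split(wval[!is.na(wval)], yr[!is.na(wval)])
    vapply(stats::setNames(nm = names(ymap)), function(yname) {
      v <- ymap[[yname]]
      ny <- lurok:::iso_weeks_in_year(as.integer(yname))
      if (length(v) >= ceiling(0.25 * ny)) mean(v) else NA_real_
    }, numeric(1))
  }
  for (s in 1:50) {
    set.seed(s)
    days <- as.character(seq(as.Date("2015-01-01"), as.Date("2015-12-31"),
                             by = "day"))
    nh <- sample(0:24, length(days), replace = TRUE,
                 prob = c(rep(0.04, 12), rep(0.036, 13)))
    keep <- nh > 0
    hr <- make_hourly_days(setNames(as.list(nh[keep]), days[keep]),
                           as.list(round(runif(sum(keep), 20, 60), 3)))
    agg <- aggregate_concentrations(hr)
    got <- stats::setNames(agg$annual$value, agg$annual$period_key)
    want <- oracle(hr)
    expect_equal(got[names(want)], want, tolerance = 1e-12)
  }
})
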