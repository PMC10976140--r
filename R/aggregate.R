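# Hierarchical temporal averaging of hourly monitor data under completeness
# criteria: hours -> days (>= 12 h present), days -> ISO weeks (>= 3 days),
# weeks -> years (>= 25% of the year's weeks), years -> long-term mean over
# whichever years are available.  Missing stays missing; no imputation.

#' Daily averages under the 12-hour completeness criterion
#'
#' A day's value is the arithmetic mean of its present hours and is missing
#' (NA) when fewer than `min_hours` hours are present.  Days are defined in
#' the local standard time of the study domain, a fixed UTC offset (+8 by
#' default).
#'
#' @param hourly data.frame with columns `site_id`, `timestamp` (POSIXct or
#'   ISO-8601 string, UTC), `pollutant`, `value`.
#' @param min_hours minimum present hours for a valid day (default 12, i.e.
#'   50% of 24).
#' @param utc_offset hours added to UTC to obtain local standard time.
#' @return a data.frame with columns `site_id`, `pollutant`, `period`
#'   ("day"), `period_key` (ISO date), `value` (NA when incomplete) and
#'   `n_contributing`.
#' @export
daily_average <- function(hourly, min_hours = 12, utc_offset = 8) {
  dt <- data.table::as.data.table(hourly)
  if (!inherits(dt$timestamp, "POSIXct")) {
    dt[, timestamp := as.POSIXct(timestamp, tz = "UTC")]
  }
  if (anyDuplicated(dt, by = c("site_id", "timestamp", "pollutant"))) {
    stop("duplicate site-hour rows in hourly input", call. = FALSE)
  }
  dt[, period_key := format(timestamp + utc_offset * 3600, "%Y-%m-%d",
                            tz = "UTC")]
  out <- dt[, .(value = mean(value), n_contributing = .N),
            by = .(site_id, pollutant, period_key)]
  out[n_contributing < min_hours, value := NA_real_]
  out[, period := "day"]
  data.table::setcolorder(out, c("site_id", "pollutant", "period",
                                 "period_key", "value", "n_contributing"))
  data.table::setorder(out, site_id, pollutant, period_key)
  as.data.frame(out)
}

iso_week_key <- function(dates) format(dates, "%G-W%V")

# Number of ISO weeks in an ISO year: 53 when Jan 1 falls on Thursday, or
# on Wednesday in a leap year; otherwise 52.
iso_weeks_in_year <- function(year) {
  jan1 <- as.Date(sprintf("%d-01-01", as.integer(year)))
  wd <- as.POSIXlt(jan1)$wday  # 0 = Sunday
  leap <- (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
  ifelse(wd == 4 | (leap & wd == 3), 53L, 52L)
}

#' Weekly averages under the 3-day completeness criterion
#'
#' A week's value is the mean of its available daily values and is missing
#' when fewer than `min_days` days are available.  Weeks are ISO-8601
#' weeks, assigned to the ISO year of their Thursday.
#'
#' @param daily output of [daily_average()].
#' @param min_days minimum available days for a valid week (default 3).
#' @return a data.frame at weekly resolution (`period` = "week",
#'   `period_key` like "2015-W07").
#' @export
weekly_average <- function(daily, min_days = 3) {
  dt <- data.table::as.data.table(daily)
  dt <- dt[!is.na(value)]
  dt[, period_key := iso_week_key(as.Date(period_key))]
  out <- dt[, .(value = mean(value), n_contributing = .N),
            by = .(site_id, pollutant, period_key)]
  out[n_contributing < min_days, value := NA_real_]
  out[, period := "week"]
  data.table::setcolorder(out, c("site_id", "pollutant", "period",
                                 "period_key", "value", "n_contributing"))
  data.table::setorder(out, site_id, pollutant, period_key)
  as.data.frame(out)
}

#' Annual averages under the 25%-of-weeks completeness criterion
#'
#' A year's value is the mean of its available weekly values and is missing
#' when fewer than `ceiling(min_frac * weeks-in-year)` weekly values are
#' available (13 of 52 by default).
#'
#' @param weekly output of [weekly_average()].
#' @param min_frac minimum fraction of the ISO year's weeks (default 0.25).
#' @return a data.frame at annual resolution (`period` = "year",
#'   `period_key` = ISO year).
#' @export
annual_average <- function(weekly, min_frac = 0.25) {
  dt <- data.table::as.data.table(weekly)
  dt <- dt[!is.na(value)]
  dt[, period_key := substr(period_key, 1, 4)]
  out <- dt[, .(value = mean(value), n_contributing = .N),
            by = .(site_id, pollutant, period_key)]
  need <- ceiling(min_frac * iso_weeks_in_year(as.integer(out$period_key)))
  out[n_contributing < need, value := NA_real_]
  out[, period := "year"]
  data.table::setcolorder(out, c("site_id", "pollutant", "period",
                                 "period_key", "value", "n_contributing"))
  data.table::setorder(out, site_id, pollutant, period_key)
  as.data.frame(out)
}

#' Long-term mean over available annual averages
#'
#' Unweighted mean of each site's available annual values over the
#' requested years; sites with no available year get NA.
#'
#' @param annual output of [annual_average()].
#' @param years integer vector of years to average over.
#' @return a data.frame with `period` = "LTM" and `period_key` like
#'   "2015-2020"; `n_contributing` counts the available years.
#' @export
long_term_mean <- function(annual, years) {
  if (length(years) == 0) stop("`years` must be nonempty", call. = FALSE)
  dt <- data.table::as.data.table(annual)
  dt <- dt[period_key %in% as.character(years)]
  key <- paste(min(years), max(years), sep = "-")
  out <- dt[, .(value = if (any(!is.na(value))) mean(value, na.rm = TRUE)
                        else NA_real_,
                n_contributing = sum(!is.na(value))),
            by = .(site_id, pollutant)]
  out[, `:=`(period = "LTM", period_key = key)]
  data.table::setcolorder(out, c("site_id", "pollutant", "period",
                                 "period_key", "value", "n_contributing"))
  data.table::setorder(out, site_id, pollutant)
  as.data.frame(out)
}

#' Full hourly-to-annual aggregation chain
#'
#' Applies [daily_average()], [weekly_average()], [annual_average()] and
#' [long_term_mean()] in sequence.
#'
#' @inheritParams daily_average
#' @param years years for the long-term mean (default: all years present).
#' @param min_days,min_frac completeness thresholds passed through.
#' @return a list with elements `daily`, `weekly`, `annual`, `ltm`.
#' @export
aggregate_concentrations <- function(hourly, min_hours = 12, min_days = 3,
                                     min_frac = 0.25, utc_offset = 8,
                                     years = NULL) {
  daily <- daily_average(hourly, min_hours = min_hours,
                         utc_offset = utc_offset)
  weekly <- weekly_average(daily, min_days = min_days)
  annual <- annual_average(weekly, min_frac = min_frac)
  if (is.null(years)) years <- sort(unique(as.integer(annual$period_key)))
  ltm <- if (length(years)) long_term_mean(annual, years)
         else annual[0, ]  # nothing aggregated to the annual level
  list(daily = daily, weekly = weekly, annual = annual, ltm = ltm)
}
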