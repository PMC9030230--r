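# Policy exposure estimators: worker-days of exposure above a PM2.5
# threshold, filtering-facepiece respirator demand, threshold-day ratios,
# and workforce / air-quality correlations.

#' Worker-days of exposure above a PM2.5 threshold
#'
#' For each month, multiplies each county's worker count (the calendar
#' month's reported employment) by the number of days that county's daily
#' mean PM2.5 met or exceeded the threshold, then sums across counties.
#' Counties with employment but no air-quality data contribute nothing and
#' are listed in the `counties_missing_air_data` attribute — the estimate
#' is a lower bound wherever monitoring coverage is incomplete.
#'
#' @param employment tibble `county_key, year, month, workers` (one row per
#'   county-month; pre-aggregate NAICS codes with [filter_naics()] and
#'   summing first).
#' @param tallies exceedance tallies from [tally_exceedances()].
#' @param threshold the threshold in µg/m³ (must be present in `tallies`).
#' @return tibble `year, month, threshold, worker_days`, with attribute
#'   `counties_missing_air_data`.
#' @export
worker_days <- function(employment, tallies, threshold) {
  tal <- tallies[abs(tallies$threshold - threshold) < 1e-9, , drop = FALSE]
  if (!nrow(tal)) stop("threshold ", threshold, " not present in tallies")
  emp <- employment |>
    dplyr::summarise(workers = sum(workers), .by = c(county_key, year, month))
  joined <- dplyr::inner_join(emp, tal, by = c("county_key", "year", "month"))
  missing_air <- setdiff(emp$county_key, tal$county_key)
  out <- joined |>
    dplyr::summarise(
      worker_days = sum(workers * days_exceeding),
      .by = c(year, month)
    ) |>
    dplyr::mutate(threshold = .env$threshold) |>
    dplyr::arrange(year, month) |>
    dplyr::relocate(year, month, threshold, worker_days)
  attr(out, "counties_missing_air_data") <- sort(missing_air)
  out
}

#' Respirator demand induced by a rule threshold
#'
#' Assumes every worker in a county uses one filtering-facepiece respirator
#' on each day the county's daily mean PM2.5 meets or exceeds the
#' threshold, with the county workforce fixed at its (rounded) annual
#' average. The assumption text in the result records the known biases:
#' counties without monitors are not counted, and not all sector workers
#' work outdoors.
#'
#' @inheritParams worker_days
#' @param year calendar year of the estimate.
#' @param rounding `"round"` (default) rounds the annual mean workforce to
#'   the nearest worker per county; `"none"` keeps it fractional.
#' @return one-row tibble `year, threshold, respirators, assumption`.
#' @export
respirator_demand <- function(employment, tallies, threshold, year,
                              rounding = c("round", "none")) {
  rounding <- match.arg(rounding)
  emp_y <- employment[employment$year == year, , drop = FALSE]
  if (!nrow(emp_y)) stop("no employment records for year ", year)
  annual <- emp_y |>
    dplyr::summarise(workers = sum(workers), .by = c(county_key, month)) |>
    dplyr::summarise(workers = mean(workers), .by = county_key)
  if (rounding == "round") annual$workers <- round_half_up(annual$workers)

  tal <- tallies[abs(tallies$threshold - threshold) < 1e-9 & tallies$year == year, ,
                 drop = FALSE]
  days_by_county <- tal |>
    dplyr::summarise(days = sum(days_exceeding), .by = county_key)
  joined <- dplyr::inner_join(annual, days_by_county, by = "county_key")
  tibble::tibble(
    year = year,
    threshold = threshold,
    respirators = sum(joined$workers * joined$days),
    assumption = paste(
      "one respirator per worker (county annual-average workforce) per day at or",
      "above the threshold; counties without PM2.5 monitors excluded;",
      "indoor workers not excluded"
    )
  )
}

#' Ratio of exceedance days between two thresholds
#'
#' Total days at or above the lower threshold divided by total days at or
#' above the higher one, summed over all counties and months supplied —
#' how many more days a lenient trigger would activate a rule than a
#' strict one. At least 1 when `t_low <= t_high` on identical coverage.
#'
#' @param tallies exceedance tallies covering both thresholds over the same
#'   county-months.
#' @param t_low,t_high the two thresholds in µg/m³.
#' @param years optional year filter.
#' @return the ratio (`NA` with a warning if the denominator is 0).
#' @export
threshold_day_ratio <- function(tallies, t_low, t_high, years = NULL) {
  if (!is.null(years)) tallies <- tallies[tallies$year %in% years, , drop = FALSE]
  total_days <- function(th) {
    rows <- abs(tallies$threshold - th) < 1e-9
    if (!any(rows)) stop("threshold ", th, " not present in tallies")
    sum(tallies$days_exceeding[rows])
  }
  num <- total_days(t_low)
  den <- total_days(t_high)
  if (den == 0) {
    warning("no days at or above the higher threshold; ratio undefined")
    return(NA_real_)
  }
  num / den
}

#' Correlation between the seasonal workforce and an air-quality metric
#'
#' Pearson product-moment correlation across the 12 calendar months between
#' a county's seasonal workforce index and a climatological monthly air
#' metric (multi-year mean of daily PM2.5, or of AQI-warning-day counts).
#' Both series are monthly climatologies, so n = 12 paired points.
#'
#' @param seasonal result of [seasonal_index()] (or any tibble with
#'   `month` and `pct_change`).
#' @param air_metric tibble with columns `month` and `value`, one row per
#'   calendar month present (months missing from either series are
#'   dropped pairwise).
#' @return one-row tibble `r, n_points, constant_series` (`r` is `NA` and
#'   flagged when either series is constant).
#' @export
workforce_airquality_correlation <- function(seasonal, air_metric) {
  joined <- dplyr::inner_join(
    seasonal[, c("month", "pct_change")],
    air_metric[, c("month", "value")],
    by = "month"
  )
  if (nrow(joined) < 3) stop("need at least 3 paired months")
  constant <- stats::sd(joined$pct_change) == 0 || stats::sd(joined$value) == 0
  tibble::tibble(
    r = if (constant) NA_real_ else stats::cor(joined$pct_change, joined$value),
    n_points = nrow(joined),
    constant_series = constant
  )
}
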