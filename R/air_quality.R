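# Monitor-level PM2.5 ingestion, county-day aggregation, and tallies of
# rule-threshold exceedance days and AQI-category days.

# AQS parameter codes carrying PM2.5 mass: 88101 (FRM/FEM) and 88502
# (non-FRM/FEM "acceptable" monitors).
PM25_PARAMETER_CODES <- c(88101L, 88502L)

#' Read monitor-level daily PM2.5 records
#'
#' Two dialects are supported. `"aqs_daily"` is the EPA Air Quality System
#' daily-summary CSV (columns `State Code`, `County Code`, `Site Num`,
#' `POC`, `Date Local`, `Arithmetic Mean`, `Parameter Code`, optionally
#' `Method Type`); rows whose parameter code is not a PM2.5 mass code
#' (88101, 88502) are dropped and counted. `"canonical"` is this package's
#' own 7-column CSV (`state_fips,county_fips,site_id,poc,date,pm25_mean,`
#' `method_class`), dates ISO-8601.
#'
#' Cleaning applied in both dialects: negative daily means are clamped to 0
#' and duplicate (site, POC, date) rows are resolved by keeping the first;
#' both events are logged to stderr.
#'
#' @param source path to a CSV file (or a connection readable by
#'   [readr::read_csv()]).
#' @param dialect `"canonical"` or `"aqs_daily"`.
#' @return tibble of monitor-day records with columns `county_key`,
#'   `state_fips`, `county_fips`, `site_id`, `poc`, `date`, `pm25_mean`,
#'   `method_class`.
#' @export
read_aqs_daily <- function(source, dialect = c("canonical", "aqs_daily")) {
  dialect <- match.arg(dialect)
  df <- readr::read_csv(source, show_col_types = FALSE, progress = FALSE)

  if (dialect == "aqs_daily") {
    required <- c("State Code", "County Code", "Site Num", "POC",
                  "Date Local", "Arithmetic Mean", "Parameter Code")
    miss <- setdiff(required, names(df))
    if (length(miss)) stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
    n0 <- nrow(df)
    df <- df[df[["Parameter Code"]] %in% PM25_PARAMETER_CODES, , drop = FALSE]
    if (nrow(df) < n0) log_event("non-PM2.5 rows dropped", n = n0 - nrow(df))
    method_class <- if ("Method Type" %in% names(df)) {
      ifelse(df[["Method Type"]] %in% c("FRM", "FEM"),
             df[["Method Type"]], "nonFRMFEM")
    } else {
      ifelse(df[["Parameter Code"]] == 88101L, "FRM", "nonFRMFEM")
    }
    df <- tibble::tibble(
      state_fips = formatC(as.character(df[["State Code"]]), width = 2, flag = "0"),
      county_fips = formatC(as.character(df[["County Code"]]), width = 3, flag = "0"),
      site_id = as.character(df[["Site Num"]]),
      poc = as.integer(df[["POC"]]),
      date = df[["Date Local"]],
      pm25_mean = as.numeric(df[["Arithmetic Mean"]]),
      method_class = method_class
    )
  } else {
    required <- c("state_fips", "county_fips", "site_id", "poc", "date",
                  "pm25_mean", "method_class")
    miss <- setdiff(required, names(df))
    if (length(miss)) stop("missing mandatory column(s): ", paste(miss, collapse = ", "))
    df <- tibble::tibble(
      state_fips = formatC(as.character(df$state_fips), width = 2, flag = "0"),
      county_fips = formatC(as.character(df$county_fips), width = 3, flag = "0"),
      site_id = as.character(df$site_id),
      poc = as.integer(df$poc),
      date = df$date,
      pm25_mean = as.numeric(df$pm25_mean),
      method_class = as.character(df$method_class)
    )
  }

  if (nrow(df)) {
    parsed <- as.Date(as.character(df$date), format = "%Y-%m-%d")
    bad <- which(is.na(parsed))
    if (length(bad)) stop("unparseable date at data row ", bad[1], ": ", df$date[bad[1]])
    df$date <- parsed
  } else {
    df$date <- as.Date(character())
  }

  n_neg <- sum(df$pm25_mean < 0, na.rm = TRUE)
  if (n_neg) {
    log_event("negative daily means clamped to 0", n = n_neg)
    df$pm25_mean[df$pm25_mean < 0] <- 0
  }

  key <- paste(df$site_id, df$poc, df$date, sep = "|")
  dup <- duplicated(key)
  if (any(dup)) {
    log_event("duplicate (site, poc, date) rows dropped, first kept", n = sum(dup))
    df <- df[!dup, , drop = FALSE]
  }

  df$county_key <- make_county_key(df$state_fips, df$county_fips)
  df[, c("county_key", "state_fips", "county_fips", "site_id", "poc",
         "date", "pm25_mean", "method_class")]
}

#' Aggregate monitor-day records to county-day mean PM2.5
#'
#' Averaging is two-stage: multiple POCs (collocated instruments) at a site
#' are first averaged into one site-day value, then site-day values are
#' averaged into the county-day mean. This keeps a multi-instrument site
#' from dominating its county. Counties and days with no monitor data are
#' absent from the output, never zero-filled.
#'
#' @param records monitor-day tibble from [read_aqs_daily()].
#' @return tibble with columns `county_key`, `date`, `pm25` (µg/m³ daily
#'   county mean) and `n_monitors` (contributing site-days).
#' @export
county_daily_average <- function(records) {
  records |>
    dplyr::summarise(
      pm25 = mean(pm25_mean),
      .by = c(county_key, site_id, date)
    ) |>
    dplyr::summarise(
      pm25 = mean(pm25),
      n_monitors = dplyr::n(),
      .by = c(county_key, date)
    ) |>
    dplyr::arrange(county_key, date)
}

#' Tally threshold-exceedance days by county and month
#'
#' A day exceeds threshold `T` when its county daily mean is `>= T`: the
#' worker-protection rule thresholds (20.5 and 55.5 µg/m³) are band lower
#' edges and trigger "at and above" the stated concentration, so the closed
#' comparison is used for all thresholds.
#'
#' @param series county-day tibble from [county_daily_average()].
#' @param thresholds numeric vector of positive thresholds in µg/m³.
#' @return tibble `county_key, year, month, threshold, days_exceeding,
#'   days_observed`, one row per county-month-threshold.
#' @export
tally_exceedances <- function(series, thresholds) {
  if (any(thresholds <= 0)) stop("thresholds must be > 0")
  thresholds <- sort(thresholds)
  base <- series |>
    dplyr::mutate(
      year = as.integer(format(date, "%Y")),
      month = as.integer(format(date, "%m"))
    )
  dplyr::bind_rows(lapply(thresholds, function(th) {
    base |>
      dplyr::summarise(
        threshold = th,
        days_exceeding = sum(pm25 >= th),
        days_observed = dplyr::n(),
        .by = c(county_key, year, month)
      )
  })) |>
    dplyr::arrange(county_key, year, month, threshold) |>
    dplyr::relocate(county_key, year, month, threshold, days_exceeding, days_observed)
}

#' Count days per AQI category by county and month
#'
#' Each observed county-day is assigned the level-of-concern label of its
#' daily-mean index value; counts partition the observed days of the
#' county-month.
#'
#' @param series county-day tibble from [county_daily_average()].
#' @param table a [breakpoint_table()] (default federal AQI).
#' @return tibble `county_key, year, month, label, days`.
#' @export
category_days <- function(series, table = default_breakpoints("AQI")) {
  series |>
    dplyr::mutate(
      year = as.integer(format(date, "%Y")),
      month = as.integer(format(date, "%m")),
      label = category_label(concentration_to_index(pm25, table), table)
    ) |>
    dplyr::summarise(days = dplyr::n(), .by = c(county_key, year, month, label)) |>
    dplyr::arrange(county_key, year, month, label)
}

#' Mean days per calendar month in each AQI category over a span of years
#'
#' For each county, calendar month and label, averages the yearly day counts
#' over the year range. With `divisor = "observed_years"` (default) the
#' divisor is the number of years in which that county-month has any
#' observed days — counties whose record starts mid-period are averaged
#' over the years they were monitored. `"all_years"` divides by the full
#' span length regardless of gaps.
#'
#' @param counts tibble from [category_days()].
#' @param years integer vector of years defining the span (e.g.
#'   `2011:2020`).
#' @param divisor `"observed_years"` or `"all_years"`.
#' @return tibble `county_key, month, label, mean_days`.
#' @export
mean_monthly_category_days <- function(counts, years,
                                       divisor = c("observed_years", "all_years")) {
  divisor <- match.arg(divisor)
  counts <- counts[counts$year %in% years, , drop = FALSE]
  if (!nrow(counts)) {
    return(tibble::tibble(county_key = character(), month = integer(),
                          label = character(), mean_days = numeric()))
  }
  obs_years <- counts |>
    dplyr::summarise(n_years = dplyr::n_distinct(year), .by = c(county_key, month))
  counts |>
    dplyr::summarise(total_days = sum(days), .by = c(county_key, month, label)) |>
    dplyr::left_join(obs_years, by = c("county_key", "month")) |>
    dplyr::mutate(
      mean_days = total_days /
        (if (divisor == "all_years") length(unique(years)) else n_years)
    ) |>
    dplyr::select(county_key, month, label, mean_days) |>
    dplyr::arrange(county_key, month, label)
}
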