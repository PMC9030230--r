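# End-to-end report assembly: from monitor-level PM2.5 and monthly
# employment files to exceedance tallies, AQI-category days, seasonal
# workforce indices and worker-days-of-exposure tables.

#' Assemble a run configuration
#'
#' @param air_file path to the PM2.5 monitor-day CSV.
#' @param employment_file path to the monthly employment CSV.
#' @param air_dialect `"canonical"` or `"aqs_daily"`.
#' @param scheme index scheme for category tallies, `"AQI"` or `"WAQA"`.
#' @param thresholds exceedance thresholds in µg/m³ (sorted ascending).
#' @param years analysis window (calendar years).
#' @param naics NAICS prefix the employment analysis is restricted to.
#' @param divisor monthly-mean divisor mode, see
#'   [mean_monthly_category_days()].
#' @param respirator_year optional year for a respirator-demand estimate
#'   (must lie inside `years`); uses the highest threshold.
#' @param out_dir directory the report CSVs are written to.
#' @return a config list of class `run_config`.
#' @export
run_config <- function(air_file, employment_file,
                       air_dialect = "canonical",
                       scheme = "AQI",
                       thresholds = c(20.5, 35, 55.5),
                       years = 2011:2020,
                       naics = "23",
                       divisor = "observed_years",
                       respirator_year = NULL,
                       out_dir = ".") {
  thresholds <- sort(thresholds)
  if (!is.null(respirator_year) && !respirator_year %in% years) {
    stop("respirator_year ", respirator_year, " lies outside the analysis years")
  }
  structure(as.list(environment()), class = "run_config")
}

#' Run the full exposure-assessment pipeline
#'
#' Reads the configured inputs, aggregates monitors to county-day PM2.5,
#' tallies threshold-exceedance and AQI-category days, computes per-county
#' seasonal workforce indices, and estimates statewide monthly worker-days
#' of exposure for every configured threshold (plus respirator demand if a
#' year is configured). Writes `tallies.csv`, `category_days.csv`,
#' `seasonal_index.csv`, `exposure.csv` and `summary.txt` to the output
#' directory and returns the tables invisibly. The analysis path draws no
#' random numbers: identical inputs give byte-identical outputs.
#'
#' @param config a [run_config()].
#' @return (invisibly) a named list of the result tibbles.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  table <- default_breakpoints(config$scheme)

  records <- read_aqs_daily(config$air_file, config$air_dialect)
  records <- records[as.integer(format(records$date, "%Y")) %in% config$years, ,
                     drop = FALSE]
  if (!nrow(records)) {
    warning("no PM2.5 records in the analysis window; tallies are empty")
  }
  series <- county_daily_average(records)

  tallies <- if (nrow(series)) tally_exceedances(series, config$thresholds) else
    tibble::tibble(county_key = character(), year = integer(), month = integer(),
                   threshold = numeric(), days_exceeding = integer(),
                   days_observed = integer())
  cats <- if (nrow(series)) category_days(series, table) else
    tibble::tibble(county_key = character(), year = integer(), month = integer(),
                   label = character(), days = integer())

  employment <- read_qcew_monthly(config$employment_file)
  employment <- filter_naics(employment, config$naics)
  employment <- employment[employment$year %in% config$years, , drop = FALSE]

  seasonal <- dplyr::bind_rows(lapply(
    split(employment, employment$county_key),
    function(rec) {
      idx <- seasonal_index(rec, config$years)
      tibble::tibble(county_key = rec$county_key[1],
                     month = idx$month,
                     mean_workers = idx$mean_workers,
                     pct_change = idx$pct_change,
                     baseline_month = attr(idx, "baseline_month"))
    }
  ))

  emp_monthly <- employment |>
    dplyr::summarise(workers = sum(workers), .by = c(county_key, year, month))
  exposure <- dplyr::bind_rows(lapply(config$thresholds, function(th) {
    if (!nrow(tallies)) return(NULL)
    worker_days(emp_monthly, tallies, th)
  }))
  missing_air <- sort(setdiff(emp_monthly$county_key, tallies$county_key))

  respirators <- if (!is.null(config$respirator_year) && nrow(tallies)) {
    respirator_demand(emp_monthly, tallies, max(config$thresholds),
                      config$respirator_year)
  }

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, name) {
    readr::write_csv(x, file.path(config$out_dir, name), progress = FALSE)
  }
  wr(tallies, "tallies.csv")
  wr(cats, "category_days.csv")
  wr(seasonal, "seasonal_index.csv")
  wr(exposure, "exposure.csv")

  summary_lines <- c(
    sprintf("analysis window: %d-%d", min(config$years), max(config$years)),
    sprintf("scheme: %s; thresholds: %s ug/m3", config$scheme,
            paste(config$thresholds, collapse = ", ")),
    sprintf("counties with air data: %d", dplyr::n_distinct(tallies$county_key)),
    sprintf("counties with employment but no air data: %s",
            if (length(missing_air)) paste(missing_air, collapse = ", ") else "none"),
    if (!is.null(respirators)) {
      sprintf("respirator demand %d at %.1f ug/m3: %d",
              respirators$year, respirators$threshold,
              as.integer(respirators$respirators))
    }
  )
  writeLines(summary_lines, file.path(config$out_dir, "summary.txt"))

  invisible(list(tallies = tallies, category_days = cats, seasonal = seasonal,
                 exposure = exposure, respirators = respirators,
                 counties_missing_air_data = missing_air))
}

#' Write simulated air and employment data as canonical CSVs
#'
#' Emits the canonical monitor-day and employment CSVs consumed by
#' [run_pipeline()] plus plain-text truth files (per-county-month episode
#' days; noiseless seasonal index) for validation harnesses.
#'
#' @param sim_air result of [simulate_pm25()].
#' @param sim_emp result of [simulate_employment()].
#' @param out_dir output directory.
#' @return (invisibly) the paths written.
#' @export
write_simulation <- function(sim_air, sim_emp, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    air = file.path(out_dir, "air_canonical.csv"),
    employment = file.path(out_dir, "employment_canonical.csv"),
    truth_episodes = file.path(out_dir, "truth_episode_days.csv"),
    truth_seasonal = file.path(out_dir, "truth_seasonal_index.csv")
  )
  air <- sim_air$records[, c("state_fips", "county_fips", "site_id", "poc",
                             "date", "pm25_mean", "method_class")]
  readr::write_csv(air, paths["air"], progress = FALSE)
  emp <- sim_emp$records
  emp$workers <- round(emp$workers)
  readr::write_csv(emp, paths["employment"], progress = FALSE)
  readr::write_csv(sim_air$truth$episode_days, paths["truth_episodes"], progress = FALSE)
  readr::write_csv(sim_emp$truth, paths["truth_seasonal"], progress = FALSE)
  invisible(paths)
}
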