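# Fixture builders and independent brute-force oracles used across tests.

# --- fixture writers ---------------------------------------------------------

write_air_csv <- function(rows, path = withr::local_tempfile(fileext = ".csv",
                                                             .local_envir = parent.frame())) {
  readr::write_csv(rows, path, progress = FALSE)
  path
}

air_rows <- function(site_id, date, pm25, county_fips = "033",
                     state_fips = "53", poc = 1L, method_class = "FRM") {
  tibble::tibble(
    state_fips = state_fips, county_fips = county_fips, site_id = site_id,
    poc = poc, date = date, pm25_mean = pm25, method_class = method_class
  )
}

emp_rows <- function(county_key, naics, year, month, workers) {
  tibble::tibble(county_key = county_key, naics = naics,
                 year = year, month = month, workers = workers)
}

# county-day tibble straight from daily values (bypasses monitor ingestion)
county_series <- function(county_key, dates, pm25) {
  tibble::tibble(county_key = county_key, date = as.Date(dates),
                 pm25 = pm25, n_monitors = 1L)
}

# --- independent oracles -----------------------------------------------------

# record-by-record group-and-mean: POC -> site-day, then site-day -> county-day
oracle_county_average <- function(records) {
  site_day <- list()
  for (i in seq_len(nrow(records))) {
    k <- paste(records$county_key[i], records$site_id[i], records$date[i])
    site_day[[k]] <- c(site_day[[k]], records$pm25_mean[i])
  }
  county_day <- list()
  for (k in names(site_day)) {
    parts <- strsplit(k, " ")[[1]]
    ck <- paste(parts[1], parts[3])
    county_day[[ck]] <- c(county_day[[ck]], mean(site_day[[k]]))
  }
  out <- data.frame(key = names(county_day),
                    pm25 = vapply(county_day, mean, numeric(1)),
                    n = vapply(county_day, length, integer(1)))
  out[order(out$key), ]
}

# scalar NowCast evaluated straight from the weight formula
oracle_nowcast <- function(hours) {
  if (length(hours) < 3 || sum(!is.na(hours[1:3])) < 2) return(NA_real_)
  num <- 0; den <- 0
  mx <- max(hours, na.rm = TRUE); mn <- min(hours, na.rm = TRUE)
  w <- if (mx > 0) max(1 - (mx - mn) / mx, 0.5) else 1
  for (i in seq_along(hours)) {
    if (!is.na(hours[i])) {
      num <- num + w^(i - 1) * hours[i]
      den <- den + w^(i - 1)
    }
  }
  # same 0.1-grid tolerance as the package's truncation convention, so the
  # comparison tests the weighting formula rather than float summation order
  floor(num / den * 10 + 1e-9) / 10
}

# Pearson r by the sum formula
oracle_pearson <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}
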