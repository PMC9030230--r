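# Synthetic monitor-level PM2.5 and monthly employment with known ground
# truth. The generator reproduces the two regimes the analysis assumes:
# a winter-elevated PM2.5 baseline (home heating, inversions) and episodic
# August/September wildfire spikes; and an employment annual cycle with a
# January trough and a summer peak, plus long-term trend and shocks.

# Deterministic per-county substream seed so adding a county (or changing
# the county list order) does not perturb other counties' draws.
substream_seed <- function(seed, key, salt = 0L) {
  h <- salt %% 2147483647
  for (code in utf8ToInt(as.character(key))) {
    h <- (h * 131 + code) %% 2147483647
  }
  as.integer((h + seed) %% 2147483647)
}

#' PM2.5 simulation scenario
#'
#' Daily latent county-mean PM2.5 is the sum of (i) a lognormal baseline
#' with the given median and geometric SD of day-to-day noise, (ii) an
#' annual cosine peaking on 1 January with the given amplitude (winter
#' elevation), and (iii) additive wildfire-episode pulses. Episode counts
#' per county-year are Poisson; each episode starts on a uniformly chosen
#' day of an eligible month, lasts a discrete-uniform number of days, and
#' adds a lognormal magnitude; overlapping episodes add. Monitors within a
#' county observe the shared latent day mean plus independent Gaussian
#' measurement noise (clamped at 0).
#'
#' Defaults emulate an eastern-Washington-like county: winter median near
#' 12 µg/m³ against a summer baseline near 6, with one to two multi-day
#' smoke episodes per year confined to August-September.
#'
#' @param county_keys character vector of county FIPS keys.
#' @param n_monitors monitors per county.
#' @param years calendar years to simulate.
#' @param baseline_median median of the lognormal baseline, µg/m³.
#' @param baseline_gsd geometric SD of the baseline (1 = no day-to-day
#'   noise).
#' @param winter_amplitude peak winter addition, µg/m³ (0 on 1 July).
#' @param episode_rate expected wildfire episodes per county-year.
#' @param episode_months calendar months eligible for episode starts.
#' @param episode_duration length-2 integer vector, discrete-uniform
#'   episode duration range in days.
#' @param episode_peak_median,episode_peak_gsd lognormal magnitude added on
#'   episode days, µg/m³.
#' @param monitor_noise_sd SD of per-monitor measurement noise, µg/m³.
#' @param forced_episodes optional tibble `county_key, start, duration,
#'   magnitude` of deterministic episodes (used for exact-recovery tests).
#' @param seed integer RNG seed.
#' @return a config list of class `pm25_scenario`.
#' @export
pm25_scenario <- function(county_keys = "53077",
                          n_monitors = 2,
                          years = 2011:2020,
                          baseline_median = 6,
                          baseline_gsd = 1.6,
                          winter_amplitude = 6,
                          episode_rate = 1.5,
                          episode_months = c(8L, 9L),
                          episode_duration = c(2L, 8L),
                          episode_peak_median = 60,
                          episode_peak_gsd = 2,
                          monitor_noise_sd = 1,
                          forced_episodes = NULL,
                          seed = 1L) {
  stopifnot(
    baseline_median >= 0, baseline_gsd >= 1, winter_amplitude >= 0,
    episode_rate >= 0, all(episode_months %in% 1:12),
    length(episode_duration) == 2, episode_duration[1] <= episode_duration[2],
    episode_peak_median >= 0, monitor_noise_sd >= 0, n_monitors >= 1
  )
  structure(as.list(environment()), class = "pm25_scenario")
}

#' Simulate monitor-level daily PM2.5 with known truth
#'
#' @param config a [pm25_scenario()].
#' @return list with `records` (canonical monitor-day tibble accepted by
#'   [county_daily_average()]), and `truth`: `latent` (tibble `county_key,
#'   date, latent_mean, episode` giving the noise-free county-day mean and
#'   whether the day is inside an episode) and `episode_days` (tibble
#'   `county_key, year, month, episode_days`).
#' @export
simulate_pm25 <- function(config) {
  stopifnot(inherits(config, "pm25_scenario"))
  dates <- seq(as.Date(paste0(min(config$years), "-01-01")),
               as.Date(paste0(max(config$years), "-12-31")), by = "day")
  doy <- as.integer(format(dates, "%j"))
  winter <- config$winter_amplitude * (1 + cos(2 * pi * (doy - 1) / 365.25)) / 2

  rec_list <- list()
  latent_list <- list()
  for (ck in config$county_keys) {
    set.seed(substream_seed(config$seed, ck))

    baseline <- if (config$baseline_gsd > 1) {
      exp(stats::rnorm(length(dates), log(config$baseline_median),
                       log(config$baseline_gsd)))
    } else {
      rep(config$baseline_median, length(dates))
    }

    episode_add <- numeric(length(dates))
    add_episode <- function(start, duration, magnitude) {
      idx <- match(seq(start, by = "day", length.out = duration), dates)
      idx <- idx[!is.na(idx)]
      episode_add[idx] <<- episode_add[idx] + magnitude
    }
    if (config$episode_rate > 0) {
      for (y in config$years) {
        n_ep <- stats::rpois(1, config$episode_rate)
        for (e in seq_len(n_ep)) {
          m <- config$episode_months[sample.int(length(config$episode_months), 1)]
          month_start <- as.Date(sprintf("%d-%02d-01", y, m))
          n_days <- as.integer(format(seq(month_start, by = "month",
                                          length.out = 2)[2] - 1, "%d"))
          start <- month_start + sample.int(n_days, 1) - 1
          duration <- config$episode_duration[1] +
            sample.int(config$episode_duration[2] - config$episode_duration[1] + 1, 1) - 1L
          magnitude <- exp(stats::rnorm(1, log(config$episode_peak_median),
                                        log(config$episode_peak_gsd)))
          add_episode(start, duration, magnitude)
        }
      }
    }
    if (!is.null(config$forced_episodes)) {
      fe <- config$forced_episodes
      for (i in which(fe$county_key == ck)) {
        add_episode(as.Date(fe$start[i]), fe$duration[i], fe$magnitude[i])
      }
    }

    latent <- baseline + winter + episode_add
    latent_list[[ck]] <- tibble::tibble(
      county_key = ck, date = dates, latent_mean = latent,
      episode = episode_add > 0
    )

    for (mon in seq_len(config$n_monitors)) {
      noise <- if (config$monitor_noise_sd > 0) {
        stats::rnorm(length(dates), 0, config$monitor_noise_sd)
      } else {
        numeric(length(dates))
      }
      rec_list[[paste(ck, mon)]] <- tibble::tibble(
        county_key = ck,
        state_fips = substr(ck, 1, 2),
        county_fips = substr(ck, 3, 5),
        site_id = sprintf("%s-%03d", ck, mon),
        poc = 1L,
        date = dates,
        pm25_mean = pmax(latent + noise, 0),
        method_class = "FEM"
      )
    }
  }

  latent <- dplyr::bind_rows(latent_list)
  episode_days <- latent |>
    dplyr::mutate(year = as.integer(format(date, "%Y")),
                  month = as.integer(format(date, "%m"))) |>
    dplyr::summarise(episode_days = sum(episode), .by = c(county_key, year, month))

  list(
    records = dplyr::bind_rows(rec_list),
    truth = list(latent = latent, episode_days = episode_days)
  )
}

#' Employment simulation scenario
#'
#' Monthly worker counts follow
#' `mean_level * (1 + trend) * (1 + seasonal(month)) + noise`, where the
#' seasonal factor is a raised cosine with its minimum in January and its
#' peak (July) `seasonal_peak_pct` percent above the January trough, the
#' trend is linear in years from the first simulated year, and an optional
#' multiplicative shock hits one year-month (e.g. a pandemic drop).
#'
#' @param county_keys character vector of county FIPS keys.
#' @param years calendar years to simulate.
#' @param mean_level January-trough workforce level (workers).
#' @param seasonal_peak_pct percent excess of the July peak over January.
#' @param trend_pct_per_year linear growth in percent per year.
#' @param noise_sd SD of additive month-to-month noise (workers).
#' @param shock optional list `(year, month, factor)`.
#' @param naics NAICS code attached to the records (default `"23"`).
#' @param seed integer RNG seed.
#' @return a config list of class `employment_scenario`.
#' @export
employment_scenario <- function(county_keys = "53077",
                                years = 2011:2020,
                                mean_level = 5000,
                                seasonal_peak_pct = 25,
                                trend_pct_per_year = 2,
                                noise_sd = 0,
                                shock = NULL,
                                naics = "23",
                                seed = 1L) {
  stopifnot(mean_level > 0, seasonal_peak_pct >= 0, noise_sd >= 0)
  structure(as.list(environment()), class = "employment_scenario")
}

#' Simulate monthly employment with known truth
#'
#' @param config an [employment_scenario()].
#' @return list with `records` (tibble `county_key, naics, year, month,
#'   workers`; worker counts are left fractional so that noiseless
#'   scenarios are exactly recoverable) and `truth` (tibble `county_key,
#'   month, pct_change`: the noiseless seasonal index).
#' @export
simulate_employment <- function(config) {
  stopifnot(inherits(config, "employment_scenario"))
  months <- 1:12
  seasonal <- config$seasonal_peak_pct / 100 * (1 - cos(2 * pi * (months - 1) / 12)) / 2

  rec_list <- list()
  truth_list <- list()
  for (ck in config$county_keys) {
    set.seed(substream_seed(config$seed, ck, salt = 7L))
    grid <- expand.grid(year = config$years, month = months)
    grid <- grid[order(grid$year, grid$month), ]
    trend <- 1 + config$trend_pct_per_year / 100 * (grid$year - min(config$years))
    workers <- config$mean_level * trend * (1 + seasonal[grid$month])
    if (config$noise_sd > 0) {
      workers <- workers + stats::rnorm(nrow(grid), 0, config$noise_sd)
    }
    if (!is.null(config$shock)) {
      hit <- grid$year == config$shock$year & grid$month == config$shock$month
      workers[hit] <- workers[hit] * config$shock$factor
    }
    rec_list[[ck]] <- tibble::tibble(
      county_key = ck, naics = config$naics,
      year = as.integer(grid$year), month = as.integer(grid$month),
      workers = pmax(workers, 0)
    )
    truth_list[[ck]] <- tibble::tibble(
      county_key = ck, month = months,
      pct_change = 100 * seasonal  # relative to the January trough
    )
  }
  list(records = dplyr::bind_rows(rec_list),
       truth = dplyr::bind_rows(truth_list))
}
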