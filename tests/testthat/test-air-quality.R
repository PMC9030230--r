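# Monitor ingestion, county-day aggregation, and exceedance/category tallies.

test_that("canonical CSV reader clamps negatives and drops duplicates", {
  rows <- air_rows(c("a", "a", "b"), c("2020-08-01", "2020-08-02", "2020-08-01"),
                   c(10, -0.2, 12))
  path <- write_air_csv(rows)
  expect_message(recs <- read_aqs_daily(path), "clamped")
  expect_equal(nrow(recs), 3)
  expect_equal(recs$pm25_mean[2], 0)
  expect_s3_class(recs$date, "Date")

  dup <- rbind(rows, rows[1, ])
  expect_message(recs2 <- read_aqs_daily(write_air_csv(dup)), "duplicate")
  expect_equal(nrow(recs2), 3)

  empty <- rows[0, ]
  expect_equal(nrow(read_aqs_daily(write_air_csv(empty))), 0)

  broken <- rows[, setdiff(names(rows), "pm25_mean")]
  expect_error(read_aqs_daily(write_air_csv(broken)), "pm25_mean")

  bad_date <- rows; bad_date$date[2] <- "08/02/2020"
  expect_error(read_aqs_daily(write_air_csv(bad_date)), "unparseable date")
})

test_that("AQS-dialect reader keeps only PM2.5 parameter rows", {
  aqs <- tibble::tibble(
    `State Code` = "53", `County Code` = "033", `Site Num` = "0080",
    POC = c(1L, 1L, 3L), `Date Local` = "2020-09-12",
    `Arithmetic Mean` = c(80.1, 12.0, 79.0),
    `Parameter Code` = c(88101L, 44201L, 88502L), # middle row is ozone
    `Method Type` = c("FRM", "FEM", "Non-FRM")
  )
  path <- write_air_csv(aqs)
  expect_message(recs <- read_aqs_daily(path, "aqs_daily"), "non-PM2.5")
  expect_equal(nrow(recs), 2)
  expect_equal(recs$method_class, c("FRM", "nonFRMFEM"))
  expect_equal(recs$county_key, c("53033", "53033"))
  expect_error(read_aqs_daily(path, "canonical"), "missing mandatory")
})

test_that("county averaging is two-stage and matches the brute-force oracle", {
  # two monitors in one county on one day
  recs <- read_aqs_daily(write_air_csv(
    air_rows(c("a", "b"), "2020-08-01", c(10, 20))))
  out <- county_daily_average(recs)
  expect_equal(out$pm25, 15)
  expect_equal(out$n_monitors, 2L)

  # POCs average within a site before sites average within the county:
  # site a has POCs (10, 30) -> 20; site b has 5 -> county (20 + 5)/2
  recs <- read_aqs_daily(write_air_csv(dplyr::bind_rows(
    air_rows("a", "2020-08-01", 10, poc = 1L),
    air_rows("a", "2020-08-01", 30, poc = 2L),
    air_rows("b", "2020-08-01", 5)
  )))
  expect_equal(county_daily_average(recs)$pm25, 12.5)

  # no cross-county mixing
  recs <- read_aqs_daily(write_air_csv(dplyr::bind_rows(
    air_rows("a", "2020-08-01", 10, county_fips = "033"),
    air_rows("b", "2020-08-01", 50, county_fips = "077")
  )))
  out <- county_daily_average(recs)
  expect_equal(nrow(out), 2)
  expect_setequal(out$pm25, c(10, 50))

  # randomized fixture against the record-by-record oracle
  set.seed(11)
  n <- 600
  recs <- tibble::tibble(
    county_key = sample(c("53033", "53063", "53077"), n, replace = TRUE),
    site_id = sample(sprintf("s%02d", 1:6), n, replace = TRUE),
    poc = sample(1:3, n, replace = TRUE),
    date = as.Date("2019-08-01") + sample(0:9, n, replace = TRUE),
    pm25_mean = round(stats::rlnorm(n, log(9), 0.8), 1)
  )
  recs <- recs[!duplicated(recs[c("county_key", "site_id", "poc", "date")]), ]
  got <- county_daily_average(recs)
  want <- oracle_county_average(recs)
  expect_equal(paste(got$county_key, got$date), want$key)
  expect_equal(got$pm25, want$pm25, tolerance = 1e-12)
  expect_equal(got$n_monitors, want$n)
})

test_that("exceedance tallies use >= and are monotone in the threshold", {
  s <- county_series("53077", c("2020-08-01", "2020-08-02", "2020-08-03"),
                     c(19.0, 20.5, 56.0))
  t <- tally_exceedances(s, c(20.5, 55.5))
  expect_equal(t$days_exceeding[t$threshold == 20.5], 2) # 20.5 counts itself
  expect_equal(t$days_exceeding[t$threshold == 55.5], 1)
  expect_equal(unique(t$days_observed), 3)

  s31 <- county_series("53077", as.Date("2020-07-01") + 0:30, rep(100, 31))
  expect_equal(tally_exceedances(s31, 55.5)$days_exceeding, 31)
  expect_equal(tally_exceedances(s31, c(200))$days_exceeding, 0)
  expect_error(tally_exceedances(s31, c(-5)), "> 0")

  set.seed(21)
  for (i in 1:20) {
    vals <- stats::rlnorm(60, log(10), 1)
    s <- county_series("x", as.Date("2019-01-01") + 0:59, vals)
    t <- tally_exceedances(s, c(5, 20.5, 35, 55.5, 150)) |>
      dplyr::arrange(year, month, threshold)
    per_month <- split(t$days_exceeding, paste(t$year, t$month))
    for (m in per_month) expect_true(all(diff(m) <= 0))
  }
})

test_that("category days partition observed days and honor the anchors", {
  s <- county_series("53077", c("2020-08-01", "2020-08-02", "2020-08-03"),
                     c(10.0, 20.5, 55.5))
  cd <- category_days(s)
  expect_equal(cd$days[cd$label == "good"], 1)
  expect_equal(cd$days[cd$label == "moderate"], 1)  # 20.5 -> AQI 69
  expect_equal(cd$days[cd$label == "unhealthy"], 1) # 55.5 -> AQI 151
  expect_equal(sum(cd$days), 3)

  set.seed(31)
  vals <- stats::rlnorm(200, log(12), 1.2)
  s <- county_series("x", as.Date("2018-01-01") + 0:199, pmin(vals, 500))
  cd <- category_days(s)
  t <- tally_exceedances(s, 20.5)
  part <- dplyr::summarise(cd, days = sum(days), .by = c(year, month))
  expect_equal(part$days, t$days_observed[order(t$year, t$month)])
})

test_that("monthly category means divide by observed years by default", {
  # 2 moderate days every August of 10 years -> mean 2
  counts <- tibble::tibble(county_key = "a", year = 2011:2020, month = 8L,
                           label = "moderate", days = 2L)
  m <- mean_monthly_category_days(counts, 2011:2020)
  expect_equal(m$mean_days, 2)

  # county observed only 4 of 10 years: divisor 4, or 10 with all_years
  counts4 <- counts[counts$year >= 2017, ]
  expect_equal(mean_monthly_category_days(counts4, 2011:2020)$mean_days, 2)
  expect_equal(
    mean_monthly_category_days(counts4, 2011:2020, divisor = "all_years")$mean_days,
    0.8)

  expect_equal(nrow(mean_monthly_category_days(counts[0, ], 2011:2020)), 0)
})
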