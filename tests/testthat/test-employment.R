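# Employment ingestion, NAICS filtering, the seasonal workforce index, and
# subsector share / outdoor-potential summaries.

test_that("QCEW quarterly layout unpivots to calendar months", {
  q <- tibble::tibble(county_key = "53033", naics = "23", year = 2020L,
                      quarter = 1L, month1_employment = 100,
                      month2_employment = 110, month3_employment = 120)
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(q, path)
  recs <- read_qcew_monthly(path)
  expect_equal(recs$month, 1:3)
  expect_equal(recs$workers, c(100L, 110L, 120L))

  q$month2_employment <- NA # suppressed cell
  readr::write_csv(q, path)
  expect_message(recs <- read_qcew_monthly(path), "dropped")
  expect_equal(nrow(recs), 2)

  canon <- emp_rows("53033", "23", 2020L, 1:5, 100L + 1:5)
  readr::write_csv(canon, path)
  expect_equal(nrow(read_qcew_monthly(path)), 5)

  readr::write_csv(dplyr::bind_rows(canon, canon[1, ]), path)
  expect_error(read_qcew_monthly(path), "duplicate")
  canon$workers[1] <- -5
  readr::write_csv(canon, path)
  expect_error(read_qcew_monthly(path), "negative")
})

test_that("NAICS filtering is purely prefix-based", {
  recs <- emp_rows("x", c("236220", "238161", "237310", "42"), 2020L, 1L, 10L)
  expect_equal(filter_naics(recs, "23")$naics,
               c("236220", "238161", "237310"))
  expect_equal(filter_naics(recs, "237")$naics, "237310")
  expect_equal(filter_naics(recs, "236220")$naics, "236220")
  expect_error(filter_naics(recs, "2"), "2-6 digits")
})

test_that("seasonal index: baseline, ties, scaling invariance, recovery", {
  flat <- emp_rows("x", "23", rep(2011:2012, each = 12), rep(1:12, 2), 100L)
  idx <- seasonal_index(flat)
  expect_equal(idx$pct_change, rep(0, 12))
  expect_equal(attr(idx, "baseline_month"), 1L) # tie -> earliest month

  # known January trough / August peak
  counts <- rep(100, 12); counts[8] <- 126.2
  recs <- emp_rows("x", "23", 2020L, 1:12, counts)
  idx <- seasonal_index(recs)
  expect_equal(attr(idx, "baseline_month"), 1L)
  expect_equal(idx$pct_change[8], 26.2, tolerance = 1e-9)

  # invariant to uniform scaling of all counts
  idx2 <- seasonal_index(dplyr::mutate(recs, workers = workers * 37))
  expect_equal(idx2$pct_change, idx$pct_change, tolerance = 1e-9)

  # noiseless sinusoid amplitude a over mean mu, minimum in January:
  # recovered peak change = 100 * 2a / (mu - a)
  mu <- 500; a <- 120
  sine <- mu - a * cos(2 * pi * (1:12 - 1) / 12)
  idx3 <- seasonal_index(emp_rows("x", "23", 2019L, 1:12, sine))
  expect_equal(max(idx3$pct_change), 100 * 2 * a / (mu - a), tolerance = 1e-9)

  expect_error(seasonal_index(emp_rows("x", "23", 2020L, 1:12, 0)),
               "degenerate baseline")
  expect_error(seasonal_index(emp_rows(c("x", "y"), "23", 2020L, 1L, 5L)),
               "single county")
})

test_that("subsector shares reproduce published 2020 construction splits", {
  # statewide worker counts by NAICS level as printed for WA construction
  recs <- emp_rows("53000", c("23", "236", "237", "238", "236220"),
                   2020L, 1L, c(199784L, 51636L, 20576L, 127573L, 18808L))
  shares <- subsector_shares(recs)
  pct <- function(code, col) shares[[col]][shares$naics == code]
  expect_equal(pct("236", "pct_of_sector"), 25.8)
  expect_equal(pct("237", "pct_of_sector"), 10.3)
  expect_equal(pct("238", "pct_of_sector"), 63.9)
  expect_equal(pct("236220", "pct_of_subsector"), 36.4)

  # three-digit shares sum to ~100 of the sector
  expect_equal(sum(shares$pct_of_sector[nchar(shares$naics) == 3]), 100,
               tolerance = 0.3)
  expect_error(subsector_shares(emp_rows("x", c("23", "42"), 2020L, 1L, 10L)),
               "sectors")
  expect_error(subsector_shares(emp_rows("x", "23", 2020L, 1L, 0L)), "total")
})

test_that("shares use period-mean worker counts over the months supplied", {
  recs <- dplyr::bind_rows(
    emp_rows("x", "236", 2020L, 1:2, c(100L, 300L)), # mean 200
    emp_rows("x", "237", 2020L, 1:2, c(200L, 200L))  # mean 200
  )
  shares <- subsector_shares(recs)
  expect_equal(shares$pct_of_sector, c(50, 50))
})

test_that("outdoor-potential summary classifies by longest prefix", {
  recs <- emp_rows("53000", c("236", "237", "238"), 2020L, 1L,
                   c(51636L, 20576L, 127573L))
  map <- tibble::tibble(naics = c("236", "237"),
                        potential = c("medium", "high"))
  out <- outdoor_potential_summary(recs, map)
  expect_equal(out$pct_of_sector[out$potential == "high"], 10.3)
  expect_equal(out$pct_of_sector[out$potential == "medium"], 25.8)
  expect_equal(out$pct_of_sector[out$potential == "unclassified"], 63.9)
  expect_equal(sum(out$workers), 199785)

  # all mapped high -> 100%
  all_high <- outdoor_potential_summary(recs, tibble::tibble(
    naics = "23", potential = "high"))
  expect_equal(all_high$pct_of_sector, 100)

  # empty map -> all unclassified
  none <- outdoor_potential_summary(recs, tibble::tibble(
    naics = character(), potential = character()))
  expect_equal(none$potential, "unclassified")
  expect_equal(none$pct_of_sector, 100)

  # shipped map covers the six-digit construction codes
  shipped <- outdoor_potential_map()
  expect_true(all(c("236220", "237310", "238161") %in% shipped$naics))
  six <- emp_rows("53000", c("236220", "237310", "238161"), 2020L, 1L,
                  c(18808L, 6550L, 1000L))
  got <- outdoor_potential_summary(six, shipped)
  expect_setequal(got$potential, c("medium", "high", "mixed"))
})
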