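# smokepolicy

Occupational wildfire-smoke exposure assessment for outdoor workforces.

Air-quality-triggered worker-protection rules (California's permanent rule,
Washington's emergency rule, Oregon's proposal) activate when ambient PM2.5
meets concentration thresholds expressed on the US EPA Air Quality Index
(AQI) or Washington's stricter Air Quality Advisory (WAQA) scale.
`smokepolicy` is for occupational-health researchers and policy analysts who
want to quantify, retrospectively, how often such rules would have applied
and how many workers they would have covered: it links regulatory air
monitoring data (EPA AQS daily summaries) with county-level monthly
employment (QCEW-style extracts) and computes the policy quantities —
threshold-exceedance days, worker-days of exposure, and respirator demand.

## The core computations

**Index conversion.** Each index is a piecewise-linear map over contiguous
concentration bands. Within the band `[C_lo, C_hi]` mapped to index values
`[I_lo, I_hi]`, a (0.1-truncated) concentration `C` converts as

    I = I_lo + (I_hi - I_lo) / (C_hi - C_lo) * (C - C_lo)

rounded half-up to an integer. The shipped AQI table is the pre-2024
federal PM2.5 table; the WAQA table uses Washington's lower cut-points, so
the same concentration reads higher: 20.5 µg/m³ is AQI 69 but WAQA 101, and
55.5 µg/m³ is AQI 151 but WAQA 173 — the "encouraged" and "required"
thresholds of Washington's emergency rule. Tables for either scheme are
validated against these published equivalences at load and rejected if they
disagree.

**NowCast.** For rules worded in terms of "current" air quality,
`nowcast()` implements the EPA weighted average of up to 12 recent hourly
concentrations, with the weight factor `w = max(1 - (max-min)/max, 0.5)`
and hour lags weighted `w^i`.

**Exposure estimators.** County-day PM2.5 series (monitor → site →
county two-stage averaging) are tallied into days per county-month at or
above each threshold; worker-days of exposure for a month are
`sum over counties of workers(county, month) × exceedance_days(county,
month)`, and respirator demand for a year assumes one filtering-facepiece
respirator per worker (county annual-average workforce) per day at or above
the threshold.

## Worked example

```r
library(smokepolicy)

# rule thresholds on both scales
concentration_to_index(20.5, default_breakpoints("AQI"))   # 69
concentration_to_index(20.5, default_breakpoints("WAQA"))  # 101
index_to_min_concentration(151, default_breakpoints("AQI"))# 55.5
nowcast(c(10, 20, 30))                                     # 15.7

# synthetic county: one forced 5-day smoke episode in August 2018
sim <- simulate_pm25(pm25_scenario(
  county_keys = "53077", n_monitors = 1, years = 2018,
  baseline_median = 5, baseline_gsd = 1, winter_amplitude = 0,
  episode_rate = 0, monitor_noise_sd = 0,
  forced_episodes = tibble::tibble(county_key = "53077",
    start = "2018-08-10", duration = 5L, magnitude = 100)))
tallies <- tally_exceedances(county_daily_average(sim$records), 55.5)
sum(tallies$days_exceeding)   # 5

employment <- tibble::tibble(county_key = "53077", naics = "23",
                             year = 2018L, month = 1:12, workers = 100L)
sum(worker_days(employment, tallies, 55.5)$worker_days)  # 500
```

The tally of 5 says the county's daily mean met the 55.5 µg/m³ "required"
threshold on exactly the five forced episode days; with a constant
workforce of 100 that is 500 worker-days on which the rule's mandatory
protections would have applied. On real AQS/QCEW extracts, `run_pipeline()`
produces the same tables statewide (tallies, AQI-category days, seasonal
workforce indices, monthly worker-days) plus a summary naming counties
excluded for lack of monitoring data; `inst/cli/smokepolicy.R` wraps the
same functions as shell subcommands.

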