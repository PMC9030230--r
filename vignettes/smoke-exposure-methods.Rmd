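---
title: "Methods: assessing workforce exposure under wildfire-smoke rules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: assessing workforce exposure under wildfire-smoke rules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smokepolicy)
```

## The problem

Several US West Coast states trigger occupational wildfire-smoke
protections off ambient PM2.5 thresholds expressed on an air-quality index
scale. Washington's emergency rule "encourages" controls at 20.5 µg/m³
(WAQA 101, AQI 69) and "requires" them at 55.5 µg/m³ (WAQA 173, AQI 151).
Whether such thresholds are well targeted depends on two seasonal cycles:
ambient PM2.5 (a winter-elevated baseline from home heating and
inversions, plus episodic August–September wildfire smoke) and the outdoor
workforce (construction employment troughs in January and peaks in
July–September). `smokepolicy` quantifies their intersection: days a rule
would have applied, and worker-days of exposure it would have covered.

## Index model

An index scheme is an ordered set of concentration bands, contiguous on a
0.1 µg/m³ grid, each mapped linearly onto a contiguous integer index band
with a level-of-concern label. Concentrations are truncated (not rounded)
to 0.1 µg/m³ before lookup; the interpolated index is rounded half-up.
Both conventions follow the EPA calculator, and both matter at band edges:
20.55 µg/m³ must read as 20.5 (index 69 on the AQI), not 20.6, and
interpolated values like 68.67 and 172.83 must round to 69 and 173.

The shipped AQI table is the pre-2024 federal PM2.5 table — the one in
force over a 2011–2020 analysis window; the 2024 revision is deliberately
out of scope. The WAQA table uses Washington's lower cut-points. Because
advisory tables are republished occasionally, `breakpoint_table()`
validates any user-supplied table for these schemes against the published
rule-threshold equivalences (AQI: 20.5→69, 35.5→101, 55.5→151; WAQA:
20.5→101, 55.5→173) and rejects tables that contradict them; validation
can only be waived for schemes a user declares non-regulatory.

The inverse map `index_to_min_concentration()` returns the smallest
grid concentration whose index reaches the target. Because integer
rounding makes the forward map a step function, the inverse is computed by
analytic inversion followed by a local grid walk, guaranteeing the
round-trip property (the result reaches the index; one 0.1 step lower does
not) rather than trusting floating-point inversion alone.

Concentrations above the top band saturate at the maximum index with a
warning rather than erroring: extreme smoke events do exceed the tabulated
range and should not abort a batch analysis.

### NowCast

`nowcast()` implements the EPA weighted average of up to 12 hourly values
(newest first): weight factor `w* = 1 - (max - min)/max` over the hours
present, floored at 0.5, with hour lag `i` weighted `w^i`. The result is
missing unless at least 2 of the 3 most recent hours are present (windows
shorter than 3 hours are missing outright), and is truncated to the 0.1
grid. An all-equal window reproduces the plain mean; high hourly
variability shrinks the effective memory toward the most recent hours.
The pipeline default is calendar-day means — a retrospective analysis can
compute true 24-h averages, which is what the daily index intends to
approximate — so the NowCast is provided for rule wordings that reference
current conditions, not used in the tallies.

## Air-quality aggregation

Monitor ingestion accepts the EPA AQS daily-summary dialect (PM2.5 mass
parameter codes 88101 and 88502 only) or a canonical 7-column CSV.
Negative daily means are clamped to zero and counted; duplicate
(site, POC, date) rows keep the first occurrence; both events are logged
to stderr, never silently absorbed.

County daily means are computed in two stages: collocated instruments
(POCs) average into a site-day value, then site-days average into the
county-day. A single-stage mean would let a site with three instruments
count three times; the two-stage form weights sites equally. Days with no
monitor data are absent, never zero-filled, and counties without monitors
never appear — downstream estimators report them as excluded rather than
imputing.

A day exceeds threshold `T` when its daily mean is `>= T`. The rule
thresholds are band lower edges ("at and above" in rule text), so the
closed comparison is the faithful reading; the 35 µg/m³ NAAQS-style
threshold uses the same rule for uniformity.

Monthly climatologies of category days divide, by default, by the number
of years in which the county-month has any observation
(`divisor = "observed_years"`): a county whose record starts mid-window is
averaged over its monitored years. The alternative `"all_years"` divides
by the window length regardless of gaps, which treats unmonitored years as
zero; both are exposed because published county summaries rarely state
which was used.

## Employment model

QCEW-style input arrives either long (one row per county-NAICS-month) or
in the quarterly layout with three month-level columns, which is
unpivoted. Suppressed (blank) cells are dropped and logged; negative
counts and duplicate keys are hard errors, since they indicate a corrupt
extract rather than a data quirk.

NAICS codes are hierarchical by prefix (sector 23 ⊃ subsector 236 ⊃
industry 236220); filtering is purely prefix-based.

The seasonal index averages each calendar month's worker count over the
window years and expresses it as percent change from the minimum month
(the baseline; ties break to the earliest calendar month). The index is
invariant to uniform scaling and to a linear trend, but deliberately not
shock-adjusted: a pandemic-year April drop stays in the climatology,
matching how such series are reported. A zero-baseline month is a
degenerate-input error, not an NaN.

Subsector shares use period-mean worker counts and are rounded half-up to
one decimal, the convention of published QCEW summary tables. Denominators
prefer an explicitly reported aggregate row (published sector totals can
differ from the sum of their rounded parts by a worker) and fall back to
summing the children. The shipped outdoor-work-potential map classifies
construction industries as high (heavy/civil: 237xxx), medium (buildings:
236xxx, plus electrical/plumbing contractors) or mixed (remaining
specialty trades), reflecting published qualitative judgement; it ships as
an editable CSV because the classification is judgement, not measurement,
and `outdoor_potential_summary()` reports unmapped codes as unclassified
rather than guessing.

## Exposure estimators

Worker-days for a month: each county's reported employment for that
calendar month times its exceedance days, summed over counties. The
estimator is bilinear in employment and days, non-increasing in the
threshold, and a lower bound wherever monitoring coverage is incomplete —
counties with workers but no monitors are listed with the result, not
imputed.

Respirator demand for a year multiplies each county's annual-average
workforce (rounded to a whole worker by default; `rounding = "none"`
keeps fractions, since published estimates rarely state the choice) by its
days at or above the threshold, assuming one filtering-facepiece
respirator per worker per qualifying day. The assumption string carried in
the result records both known biases: unmonitored counties under-count,
indoor workers over-count.

The threshold-day ratio divides total days at the lenient threshold by
total days at the strict one over identical county-month coverage — a
single number for "how much more often would the lenient trigger fire".
A zero denominator yields a flagged `NA`, not an error.

Workforce–air-quality correlations are Pearson r over 12 climatological
monthly points (the seasonal index exists only as 12 calendar-month
values, so a 120-county-month mode would mix scales); constant series are
flagged undefined rather than erroring, since a flat air metric is a
legitimate outcome for clean counties.

## Synthetic-data generator

`simulate_pm25()` builds county-day latent PM2.5 as lognormal baseline
noise around a median, plus an annual cosine peaking on 1 January (winter
elevation), plus additive episode pulses: episode counts per county-year
are Poisson, starts uniform within the eligible months (default
August–September), durations discrete-uniform, magnitudes lognormal, and
overlapping episodes add. Monitors share the latent county-day mean plus
independent Gaussian measurement noise clamped at zero. Defaults
(baseline median 6 µg/m³, geometric SD 1.6, winter amplitude 6 µg/m³ —
winter medians near 12 against summer ~6 —, 1.5 episodes/year of 2–8 days
peaking near 60 µg/m³) emulate an eastern-Washington-like county with
both regimes the analysis must distinguish: elevated winter medians and
episodic late-summer extremes.

`simulate_employment()` builds monthly counts as
`level × (1 + trend) × (1 + seasonal)` with a raised-cosine seasonal term
(January trough, July peak, peak excess 25% by default — inside the
9.4–42.7% range typical of county construction workforces), linear trend,
additive noise, and an optional one-month multiplicative shock. Worker
counts are left fractional in the truth-bearing records so noiseless
scenarios are exactly recoverable; the CSV writer rounds.

Randomness is confined to the generator. Each county draws from a
substream seeded by hashing its key with the scenario seed, so adding a
county (or reordering the list) leaves other counties' draws bit-identical
— a property the tests assert. The analysis path draws no random numbers
at all; identical inputs give byte-identical outputs.

What the generator does *not* emulate: spatial correlation between
counties, atmospheric transport, diurnal structure within days,
instrument-specific bias between FRM/FEM classes, and employment
disclosure suppression. Passing recovery tests therefore demonstrate
correctness of the estimators' arithmetic and plumbing on data with the
assumed seasonal/episodic structure — not robustness to the measurement
pathologies of real AQS or QCEW extracts.

## Validation design and problem sizes

Every estimator is checked along two routes: the package path and an
independent brute-force oracle (record-by-record group-and-mean for county
averaging; the Σ-formula for Pearson r; a scalar loop over the weight
formula for NowCast), on fixtures of up to ~1000 records. Ground-truth
recovery uses noise-off scenarios where every downstream statistic is
known exactly by construction (a forced 5-day episode must yield exactly 5
exceedance days and, with 100 workers, exactly 500 worker-days).
Statistical behaviour is checked on 200 simulated years (mean episode-day
count within three standard errors of the configured expectation, with a
low rate and fixed duration so episode overlap is negligible), and
threshold monotonicity on 50 random one-county scenarios. These sizes make
the full suite run in well under a minute while leaving the statistical
checks adequately powered.

## Limitations

County-mean regulatory monitors are a crude exposure proxy for any
individual worksite; counties without monitors drop out of every estimate
rather than being interpolated (interpolation is a different method, not a
default worth hiding); the respirator estimator knowingly ignores indoor
work shares and voluntary-use behaviour; and the shipped outdoor-potential
classification covers the construction sector's published industry rows
only — users studying other sectors must supply their own map.
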