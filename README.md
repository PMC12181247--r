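# fjordwave

Hydrographic anomaly detection and abiotic–biotic coupling statistics for
coastal observatory time series.

High-latitude coastal ecosystems respond to short, sharp hydrographic
events — marine heat waves, cold spells, salinity excursions — at least as
strongly as to long-term trends, but linking such events to community-level
responses requires year-round, high-frequency observation of both the water
column and the fauna. `fjordwave` implements the full analysis chain for
cabled-observatory records of this kind: daily temperature and salinity
series on the abiotic side, weekly stereoscopic image surveys of the
shallow-water community on the biotic side.

## What it computes

**Percentile climatology and event detection.** For each day of year *d*,
values within ±5 days of *d* are pooled across all years and summarized by
their mean and 10th/90th percentiles (sort with linear interpolation;
curves optionally smoothed by a 31-day circular moving average). A marine
heat wave is a run of at least 5 consecutive days with the daily value
above the upper envelope; a cold spell, below the lower envelope. Each
event carries its *day-degrees* — the cumulative daily departure from a
baseline curve, `Σ_t (x_t − b_t)` in °C·days — against both the
climatological mean and the crossed percentile threshold. Salinity
anomalies use the identical machinery.

**CPUE standardization.** Weekly organism counts per biotic group are
standardized to catch per unit effort at the nominal weekly effort of 336
stereoscopic image pairs (2 pairs h⁻¹ × 24 h × 7 d):
`CPUE = count × 336 / effort`. Weekly biotic anomalies are detected with a
week-of-year percentile climatology and a one-week minimum duration (a
full sweep of the water column takes the camera system seven days).

**Cohort-year aggregation and coupling.** Anomalies are accumulated within
polar cohort years (01 August – 31 July). Per cohort year the package
reports positive, negative and net anomaly sums; Mann–Kendall τ with
tie-corrected variance (exact null distribution for n ≤ 10) tests for
trends in anomaly frequency and intensity; and the abiotic–biotic coupling
is estimated by OLS on rank-transformed net sums,
`rank(biotic) = α + β·rank(abiotic)`, with *F*(1, n−2), *t*, r² and
adjusted r². For untied ranks of length 8 the slope obeys
`β = 1 − Σd²/84`, with `d` the rank differences.

**Synthetic scenarios.** A generator produces complete observatory
datasets with known ground truth — seasonal sinusoids plus AR(1) noise and
injected event boxcars for the abiotic side; winter-peaked, negative
binomial weekly counts whose expectation couples to cohort-level
temperature day-degrees via `exp(β·z)` on the biotic side — so every
downstream stage can be validated end to end.

## Worked example

```r
library(fjordwave)

cfg <- system.file("extdata", "demo_scenario.yaml", package = "fjordwave")
res <- run_pipeline(cfg, "demo_run")

head(res$cohort_summaries[res$cohort_summaries$variable == "temperature", ])
#>   cohort_year    variable positive_sum negative_sum     net_sum n_anomaly_units
#> 1        2012 temperature    1.9513352  -1.35878758   0.5925476              11
#> 2        2013 temperature   11.1671605   0.00000000  11.1671605              16
#> 3        2014 temperature   27.5023553  -0.03983443  27.4625209              27
#> 4        2015 temperature    1.6660344 -14.76947765 -13.1034433              29

res$regressions[res$regressions$configuration %in% c("TOTAL", "no_jellyfish"), ]
#>    configuration n     slope  t_value      F        r2    adj_r2     p_value
#> 1          TOTAL 8 0.9047619 5.203364 27.075 0.8185941 0.7883598 0.002008276
#> 10  no_jellyfish 8 0.9047619 5.203364 27.075 0.8185941 0.7883598 0.002008276
```

The demo scenario injects warm events into four of its eight cohort years
and cold events into the other four, and couples community abundance to
the resulting cohort day-degrees (β = 0.8). The cohort table shows the
warm-dominated years (2013, 2014, 2016) with positive net °C·days and the
cold-dominated years (2015, 2018, 2019) negative; the rank regression of
community CPUE anomalies on temperature anomalies recovers a strongly
positive slope (0.90, p ≈ 0.002), which persists when the jellyfish group
is excluded and the community total is rebuilt from the remaining groups.

Individual stages are plain functions: `build_climatology()`,
`detect_events()`, `compute_weekly_cpue()`, `cohort_cumulative()`,
`mann_kendall()`, `rank_regression()`, `coupling_analysis()`. A
command-line wrapper lives at `inst/scripts/run_pipeline.R`.

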