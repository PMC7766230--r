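# roadcast

Next-day (24-hour) forecasting of roadside pollutant concentrations —
PM2.5 and CO — from hourly monitoring-station records.

Roadside air quality is driven by traffic, and traffic is periodic: CO
shows a diurnal double peak at the morning and evening rush hours, PM2.5
shows the same double peak delayed by about an hour, and daily means carry
a 7-day cycle. `roadcast` implements an LSTM encoder–decoder (Seq2Seq)
forecaster whose input stacks, hour for hour, the previous day's
air-quality and meteorology channels **plus the target pollutant's hourly
values from one week before the forecast day** — a weekly-periodicity
channel that tells the decoder what kind of day it is forecasting. The
package is for researchers in environmental health and air-quality
modelling who want a self-contained, fully testable implementation of this
model family, its baselines, and the periodicity diagnostics that motivate
it.

## What is inside

* **Periodicity diagnostics** — the biased autocorrelation
  `r_k = c_k / c_0` with `c_k = (1/T) Σ (y_t − ȳ)(y_{t+k} − ȳ)` and a
  ±1.96/√T white-noise band (`acf_profile`), hour-of-day and day-of-week
  concentration profiles (`diurnal_profile`, `weekly_profile`), and
  candidate-lag period detection (`detect_period`).
* **Models** — the weekly-periodicity Seq2Seq, a plain Seq2Seq, and
  bidirectional-LSTM / LSTM baselines, built on an LSTM cell with logistic
  gates `i, f, o`, candidate state `tanh`, `c_t = f∗c_{t−1} + i∗c̃_t`,
  `h_t = o∗tanh c_t`. Forward pass, backpropagation through time and the
  Adam optimiser are implemented in batched base-R matrix arithmetic and
  verified against scalar-loop oracles and finite differences.
* **Pipeline** — hourly station CSV I/O with strict format checking, short-gap
  linear imputation, chronological day-aligned splitting, train-only
  min-max/z-score scaling, composite 24×F windowing
  (`build_samples`), and pooled RMSE / NMSE / Pearson-r evaluation with
  multi-seed model-comparison (`compare_models`) and input-ablation
  (`ablation`) protocols.
* **Synthetic generator** — seeded roadside-station series with rush-hour
  diurnal peaks, a configurable 1-hour PM2.5 lag behind CO, weekly
  modulation, meteorology coupling, AR(1) noise and missing cells
  (`generate_station`, `generate_fleet`), so every stage is testable
  without any external data.

## Worked example

```r
library(roadcast)

## a 120-day synthetic roadside record (hourly, 2% missing cells)
station <- generate_station(synth_config(n_days = 120, seed = 7))
station
#> station_series 'S01': 2880 hours (2015-03-02 00:00 .. 2015-06-29 23:00), 2.0% cells missing

## rush-hour structure: CO peaks 08/18 h, PM2.5 delayed one hour
## (noise-free draw of the same configuration, where the peaks are exact)
clean <- generate_station(synth_config(n_days = 120, seed = 7, noise_sd = 0,
  meteo_coupling = setNames(rep(list(numeric(0)), 6), pollutant_channels())))
profile_peaks(diurnal_profile(clean, "co"))
#> [1]  8 18
profile_peaks(diurnal_profile(clean, "pm25"))
#> [1]  9 19

## the CO series has a clear 24-hour period
a <- acf_profile(station$data$co, 72)
a
#> acf_result: T = 2812, lags 0..72, 95% band +/- 0.0370
detect_period(a, c(12L, 24L, 48L))
#> [1] 24

## weekly signature of PM2.5 daily means (Monday-first)
round(weekly_profile(station, "pm25")$mean, 1)
#> [1] 44.4 41.1 42.6 43.3 45.8 44.0 47.5

## end-to-end forecast experiment: impute, split 70/15/15, scale on train,
## window, train the weekly-periodicity Seq2Seq, evaluate on the test days
res <- run_experiment(station, "pm25", "seq2seq_weekly",
                      cfg = train_config(epochs = 60, patience = 10, seed = 1),
                      hidden_size = 32)
str(res$metrics)
#> List of 5
#>  $ rmse     : num 11.7
#>  $ nmse     : num 0.0721
#>  $ pearson_r: num 0.25
#>  $ n        : int 432
#>  $ pooling  : chr "pooled_hours"
```

The metrics pool all 432 test hours (18 forecast days × 24 hours): an RMSE
of 11.7 µg/m³ against a test-period standard deviation near 12.6, an NMSE
of 0.072, and a correlation of 0.25 — on a record whose noise floor (AR(1)
noise with stationary standard deviation 10 µg/m³) bounds what any
forecaster can reach. `compare_models()` repeats such runs over variants
and seeds; on strongly weekly-modulated series the weekly-periodicity
variant has the lowest median test RMSE of the four variants, and on
series with no weekly structure it performs on par with the plain Seq2Seq
(both properties are asserted by the test suite).

## Command line

A thin wrapper over the same functions is installed at
`inst/cli/roadcast`:

```sh
roadcast simulate --out station.csv --seed 7 --n-days 120
roadcast acf      --input station.csv --channel co --max-lag 72 --out acf.json
roadcast train    --input station.csv --target pm25 --seed 1 --out model.rds
roadcast evaluate --input station.csv --n-seeds 5 --out comparison.csv
```

Each command writes a JSON run manifest (options, config snapshot, package
version, output checksums) next to its artifacts.

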