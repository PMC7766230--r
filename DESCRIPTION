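Package: roadcast
Title: Weekly-Periodicity Sequence-to-Sequence Forecasting of Roadside Air Pollutants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for next-day (24-hour) forecasting of roadside pollutant
    concentrations (PM2.5, CO) from hourly station records. Implements an
    LSTM encoder-decoder (Seq2Seq) forecaster augmented with a week-ago
    pollutant input channel that injects the weekly periodicity of
    traffic-driven pollution, together with the diagnostics that motivate
    it: biased autocorrelation with white-noise confidence bands, diurnal
    and weekly concentration profiles, and period detection. Includes
    baseline models (plain Seq2Seq, bidirectional LSTM, LSTM), forecast
    metrics (RMSE, NMSE, Pearson r), model-comparison and input-ablation
    protocols, chronological splitting and min-max/z-score scaling, hourly
    station CSV input/output with gap imputation, and a seeded synthetic
    roadside-station generator with rush-hour diurnal double peaks, weekly
    modulation, meteorology coupling, AR(1) noise and missing values.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
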