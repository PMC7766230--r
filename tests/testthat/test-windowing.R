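test_that("sample counts follow the day-offset arithmetic", {
  sc <- fit_scaler(toy_series(8))
  spec <- window_spec("pm25")
  expect_length(build_samples(toy_series(8), spec, sc), 1)
  expect_length(build_samples(toy_series(30), spec, sc), 23)
  expect_error(build_samples(toy_series(7), spec, sc), "8 complete days")
  expect_error(build_samples(toy_series(10), spec, list()), "not been fitted")
})

test_that("feature count follows the feature set and the weekly channel toggle", {
  widths <- c(target_only = 2L, pol = 6L, meo = 7L, all = 11L)
  for (fs in names(widths)) {
    without <- window_spec("pm25", fs, include_weekly_channel = FALSE)
    with <- window_spec("pm25", fs, include_weekly_channel = TRUE)
    expect_identical(n_features(without), widths[[fs]])
    expect_identical(n_features(with), widths[[fs]] + 1L)
  }
})

test_that("rows are hour-aligned and the weekly channel unscales to day T-7", {
  s <- generate_station(synth_config(n_days = 20, missing_rate = 0, seed = 8))
  scaler <- fit_scaler(s)
  spec <- window_spec("pm25", "all")
  samples <- build_samples(s, spec, scaler)
  dates <- series_date <- as.Date(format(s$time, "%Y-%m-%d"))
  for (smp in samples[c(1, length(samples))]) {
    wk_col <- which(colnames(smp$x) == "pm25_t-7")
    raw_wk <- unscale_values(scaler, smp$x[, wk_col], "pm25")
    expect_equal(raw_wk, s$data$pm25[dates == smp$target_date - 7],
                 tolerance = 1e-9)
    aq_rows <- which(dates == smp$target_date - 1)
    raw_co <- unscale_values(scaler, smp$x[, "co_t-1"], "co")
    expect_equal(raw_co, s$data$co[aq_rows], tolerance = 1e-9)
    # y is the scaled target of day T, hour for hour
    expect_equal(unscale_values(scaler, smp$y, "pm25"), smp$y_raw,
                 tolerance = 1e-9)
    expect_equal(smp$y_raw, s$data$pm25[dates == smp$target_date])
  }
})

test_that("windows touching gaps are dropped whole, matching brute-force enumeration", {
  s <- generate_station(synth_config(n_days = 30, missing_rate = 0, seed = 8))
  dates <- as.Date(format(s$time, "%Y-%m-%d"))
  udays <- unique(dates)
  # knock out one target-channel hour on day 12 and one CO hour on day 20
  s$data$pm25[which(dates == udays[12])[5]] <- NA
  s$data$co[which(dates == udays[20])[17]] <- NA
  scaler <- fit_scaler(s)
  samples <- build_samples(s, window_spec("pm25", "all"), scaler)
  # brute force: T usable iff pm25 complete on T and T-7, all features on T-1
  usable <- vapply(8:30, function(d) {
    pm_ok <- function(dd) !anyNA(s$data$pm25[dates == udays[dd]])
    day_ok <- !anyNA(s$data[dates == udays[d - 1],
                            c(pollutant_channels(), meo_feature_channels())])
    pm_ok(d) && pm_ok(d - 7) && day_ok
  }, logical(1))
  expect_length(samples, sum(usable))
  got_dates <- as.Date(vapply(samples, function(x) as.character(x$target_date), ""))
  expect_identical(got_dates, udays[8:30][usable])
})

test_that("the weekly channel changes x only, never y", {
  s <- generate_station(synth_config(n_days = 15, missing_rate = 0, seed = 2))
  scaler <- fit_scaler(s)
  with_wk <- build_samples(s, window_spec("co", "all", TRUE), scaler)
  without <- build_samples(s, window_spec("co", "all", FALSE), scaler)
  expect_length(with_wk, length(without))
  for (i in seq_along(with_wk)) {
    expect_identical(with_wk[[i]]$y, without[[i]]$y)
    expect_identical(ncol(with_wk[[i]]$x), ncol(without[[i]]$x) + 1L)
  }
})

test_that("same-day inputs are refused unless leakage is explicit", {
  expect_error(window_spec("pm25", aq_day_offset = 0), "leak")
  spec <- window_spec("pm25", aq_day_offset = 0, allow_leakage = TRUE)
  expect_identical(spec$aq_day_offset, 0L)
  expect_error(window_spec("pm25", weekly_day_offset = 7), "negative")
})
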