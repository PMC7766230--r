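#' @keywords internal
"_PACKAGE"

## Channel vocabulary --------------------------------------------------------

#' Pollutant and meteorology channel names
#'
#' `pollutant_channels()` returns the six hourly pollutant channels carried by
#' a station record; `meteo_channels()` the six meteorological covariates.
#' `meo_feature_channels()` is the subset of meteorology used as model input
#' features (wind direction, a circular variable, is recorded but not fed to
#' the forecaster).
#'
#' Units: pm25 and pm10 in micrograms per cubic metre, co in milligrams per
#' cubic metre, no2/o3/so2 in micrograms per cubic metre; temp in degrees
#' Celsius, rh in percent, pressure in hPa, wind_speed in m/s, wind_dir in
#' degrees, precip in mm/h.
#'
#' @return Character vector of channel names.
#' @export
pollutant_channels <- function() c("pm25", "pm10", "co", "no2", "o3", "so2")

#' @rdname pollutant_channels
#' @export
meteo_channels <- function() c("temp", "rh", "pressure", "wind_speed", "wind_dir", "precip")

#' @rdname pollutant_channels
#' @export
meo_feature_channels <- function() c("temp", "rh", "pressure", "wind_speed", "precip")

all_channels <- function() c(pollutant_channels(), meteo_channels())

## StationSeries -------------------------------------------------------------

#' Construct an hourly station series
#'
#' A `station_series` holds one monitoring station's hourly record: six
#' pollutant channels and six meteorological covariates on a strictly
#' contiguous hourly time axis. Missing observations are `NA`; the missing
#' mask is implicit in the `NA` pattern.
#'
#' @param station_id Character station identifier.
#' @param time `POSIXct` vector of hourly timestamps (timezone-naive local
#'   clock time, represented in UTC), strictly increasing at a 1-hour step.
#' @param data Data frame with one row per timestamp and exactly the columns
#'   named by [pollutant_channels()] and [meteo_channels()]; `NA` marks a
#'   missing cell. Non-missing pollutant concentrations must be non-negative.
#'
#' @return An object of class `station_series`.
#' @export
station_series <- function(station_id, time, data) {
  if (!is.character(station_id) || length(station_id) != 1L)
    stop("station_id must be a single string", call. = FALSE)
  if (!inherits(time, "POSIXct"))
    stop("time must be POSIXct", call. = FALSE)
  data <- as.data.frame(data)
  missing_cols <- setdiff(all_channels(), names(data))
  if (length(missing_cols))
    stop("data is missing channel columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  data <- data[all_channels()]
  if (nrow(data) != length(time))
    stop("data and time lengths differ", call. = FALSE)
  if (length(time) > 1L) {
    steps <- as.numeric(diff(time), units = "hours")
    if (any(abs(steps - 1) > 1e-9))
      stop("timestamps must be contiguous at a 1-hour step", call. = FALSE)
  }
  for (ch in pollutant_channels()) {
    v <- data[[ch]]
    if (any(v < 0, na.rm = TRUE))
      stop("negative concentration in channel '", ch, "'", call. = FALSE)
  }
  structure(
    list(station_id = station_id, time = time, data = data),
    class = "station_series"
  )
}

#' @export
print.station_series <- function(x, ...) {
  n <- length(x$time)
  n_na <- sum(is.na(as.matrix(x$data)))
  cat(sprintf(
    "station_series '%s': %d hours (%s .. %s), %.1f%% cells missing\n",
    x$station_id, n,
    format(x$time[1], "%Y-%m-%d %H:00"), format(x$time[n], "%Y-%m-%d %H:00"),
    100 * n_na / max(1L, n * ncol(x$data))
  ))
  invisible(x)
}

#' @export
length.station_series <- function(x) length(x$time)

#' Number of complete hours / days spanned by a series
#' @param series A [station_series()].
#' @return Integer count.
#' @export
n_hours <- function(series) length(series$time)

#' @rdname n_hours
#' @export
n_days <- function(series) n_hours(series) %/% 24L

## time helpers: hour-of-day 0..23, day-of-week 1..7 Monday-first, date
hour_of_day <- function(time) as.POSIXlt(time, tz = "UTC")$hour

day_of_week <- function(time) {
  # POSIXlt wday: 0 = Sunday; remap so 1 = Monday .. 7 = Sunday
  (as.POSIXlt(time, tz = "UTC")$wday + 6L) %% 7L + 1L
}

series_date <- function(time) as.Date(time, tz = "UTC")

#' Extract a contiguous sub-series by row indices
#' @noRd
subset_series <- function(series, idx) {
  station_series(series$station_id, series$time[idx], series$data[idx, , drop = FALSE])
}

make_hourly_time <- function(start_date, n_hours) {
  t0 <- as.POSIXct(paste(start_date, "00:00:00"), tz = "UTC")
  t0 + 3600 * (seq_len(n_hours) - 1)
}
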