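## Periodicity diagnostics: autocorrelation with a white-noise confidence
## band, diurnal and weekly concentration profiles, and period detection.

#' Autocorrelation function with a white-noise confidence band
#'
#' Computes the biased sample autocorrelation
#' \deqn{r_k = c_k / c_0, \quad
#'       c_k = \frac{1}{T}\sum_{t=1}^{T-k} (y_t - \bar y)(y_{t+k} - \bar y)}
#' with a single global mean and 1/T normalisation, for lags 0..`max_lag`,
#' together with the 95% white-noise band `1.96 / sqrt(T)`. The biased
#' estimator guarantees `r_0 = 1` and `|r_k| <= 1`.
#'
#' Missing values are dropped listwise (the complete subsequence is used);
#' the estimator assumes a gap-free series, and imputation would bias `r_k`.
#'
#' @param values Numeric vector; `NA`s are removed.
#' @param max_lag Largest lag `K >= 1`; needs at least `K + 2` non-missing
#'   values.
#' @return An object of class `acf_result` with fields `lag` (0..K), `r`,
#'   `T`, `conf`.
#' @export
acf_profile <- function(values, max_lag) {
  if (max_lag < 1) stop("max_lag must be >= 1", call. = FALSE)
  y <- values[!is.na(values)]
  T_ <- length(y)
  if (T_ < max_lag + 2)
    stop("series too short: need at least max_lag + 2 non-missing values",
         call. = FALSE)
  d <- y - mean(y)
  c0 <- sum(d^2) / T_
  if (c0 == 0) stop("degenerate variance: series is constant", call. = FALSE)
  r <- vapply(0:max_lag, function(k) {
    sum(d[seq_len(T_ - k)] * d[(k + 1):T_]) / T_ / c0
  }, numeric(1))
  structure(list(lag = 0:max_lag, r = r, T = T_, conf = 1.96 / sqrt(T_)),
            class = "acf_result")
}

#' @export
print.acf_result <- function(x, ...) {
  cat(sprintf("acf_result: T = %d, lags 0..%d, 95%% band +/- %.4f\n",
              x$T, max(x$lag), x$conf))
  invisible(x)
}

#' Mean concentration by hour of day
#'
#' Entry `h + 1` is the mean of all non-missing observations of `pollutant`
#' at clock hour `h` (0..23). Roadside series typically show two rush-hour
#' peaks, with the particulate peaks lagging the CO peaks by about an hour.
#'
#' @param series A [station_series()].
#' @param pollutant One of [pollutant_channels()].
#' @return Object of class `diurnal_profile`: `mean` (24), `n` (24),
#'   `pollutant`.
#' @export
diurnal_profile <- function(series, pollutant) {
  pollutant <- match.arg(pollutant, pollutant_channels())
  v <- series$data[[pollutant]]
  h <- hour_of_day(series$time)
  ok <- !is.na(v)
  n <- vapply(0:23, function(hh) sum(ok & h == hh), integer(1))
  if (any(n == 0))
    stop("coverage error: no observations at hour ", which(n == 0)[1] - 1L,
         call. = FALSE)
  m <- vapply(0:23, function(hh) mean(v[ok & h == hh]), numeric(1))
  structure(list(mean = m, n = n, pollutant = pollutant),
            class = "diurnal_profile")
}

#' Daily mean series of one pollutant
#'
#' Mean of the non-missing hourly values per calendar day; days with no
#' observation at all are dropped.
#'
#' @inheritParams diurnal_profile
#' @return Data frame with columns `date`, `value`, `n_hours`.
#' @export
daily_means <- function(series, pollutant) {
  pollutant <- match.arg(pollutant, pollutant_channels())
  v <- series$data[[pollutant]]
  d <- series_date(series$time)
  ok <- !is.na(v)
  agg <- tapply(v[ok], d[ok], mean)
  cnt <- tapply(v[ok], d[ok], length)
  data.frame(date = as.Date(names(agg)), value = as.numeric(agg),
             n_hours = as.integer(cnt), row.names = NULL)
}

#' Mean daily concentration by day of week
#'
#' Computes the daily means of `pollutant` and averages them per day of week,
#' Monday first. This is the weekly signature of traffic-driven pollution
#' (e.g. Friday/Sunday peaks and a Tuesday valley).
#'
#' @inheritParams diurnal_profile
#' @return Object of class `weekly_profile`: `mean` (7, Monday-first), `n`
#'   (days contributing), `pollutant`.
#' @export
weekly_profile <- function(series, pollutant) {
  dm <- daily_means(series, pollutant)
  dow <- day_of_week(as.POSIXct(paste(dm$date, "00:00:00"), tz = "UTC"))
  n <- vapply(1:7, function(d) sum(dow == d), integer(1))
  if (any(n == 0))
    stop("coverage error: no observations on day-of-week ", which(n == 0)[1],
         " (Monday-first)", call. = FALSE)
  m <- vapply(1:7, function(d) mean(dm$value[dow == d]), numeric(1))
  structure(list(mean = m, n = n, pollutant = pollutant),
            class = "weekly_profile")
}

#' Peak hours of a diurnal profile
#'
#' Circular local maxima of the 24-hour mean profile: hours whose mean
#' strictly exceeds both neighbours (wrapping midnight). For a rush-hour
#' double-peak profile these are the two peak hours.
#'
#' @param profile A [diurnal_profile()].
#' @return Integer vector of peak hours (0..23), ascending.
#' @export
profile_peaks <- function(profile) {
  m <- profile$mean
  left <- m[c(24, 1:23)]
  right <- m[c(2:24, 1)]
  sort(which(m > left & m > right) - 1L)
}

#' Detect a period among candidate lags
#'
#' Returns the candidate lag with the largest autocorrelation if that value
#' exceeds the white-noise confidence bound, otherwise `NULL` (no significant
#' periodicity).
#'
#' @param acf_result An [acf_profile()] result.
#' @param candidate_lags Integer lags, each >= 2 and within the computed
#'   range.
#' @return The detected lag, or `NULL`.
#' @export
detect_period <- function(acf_result, candidate_lags) {
  if (!inherits(acf_result, "acf_result"))
    stop("acf_result must come from acf_profile()", call. = FALSE)
  if (any(candidate_lags < 2) || any(!(candidate_lags %in% acf_result$lag)))
    stop("candidate_lags must be >= 2 and within the computed lags", call. = FALSE)
  r_cand <- acf_result$r[match(candidate_lags, acf_result$lag)]
  best <- which.max(r_cand)
  if (r_cand[best] > acf_result$conf) candidate_lags[best] else NULL
}
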