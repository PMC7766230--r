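## Composite 24-step training windows: previous-day air quality, previous-day
## meteorology, and the week-ago target pollutant, paired with the next-day
## 24-hour target.

#' Windowing specification
#'
#' Describes how one forecast-day sample is assembled. The encoder input is a
#' 24 x F matrix whose row `h` stacks, hour-for-hour, the selected channels
#' of the offset days; the target is the 24 hourly values of
#' `target_pollutant` on the forecast day T.
#'
#' Feature sets follow the input-ablation protocol: `target_only` = PM2.5 and
#' CO; `pol` adds the other four pollutants (PM10, SO2, NO2, O3); `meo` adds
#' the five meteorology channels to PM2.5 and CO; `all` uses all six
#' pollutants plus meteorology. The weekly channel is the target pollutant at
#' day T-7 and is what injects the weekly periodicity.
#'
#' Air-quality and weekly day offsets must be negative: a same-day (offset
#' 0) air-quality input would hand the model the answer. Set `allow_leakage
#' = TRUE` only to reproduce that literal (leaky) configuration in
#' reproduction studies. Meteorology is exogenous — in operational use it
#' comes from a numerical weather forecast (WRF-style) — so
#' `meo_day_offset = 0` is a legitimate forecast-day configuration and is
#' allowed without the leakage flag.
#'
#' @param target_pollutant `"pm25"` or `"co"`.
#' @param feature_set One of `"all"`, `"target_only"`, `"pol"`, `"meo"`.
#' @param include_weekly_channel Add the day T-7 target-pollutant channel?
#' @param aq_day_offset,meo_day_offset,weekly_day_offset Day offsets (in
#'   days, relative to forecast day T) of the pollutant block, the
#'   meteorology block, and the weekly channel. Defaults -1, -1, -7.
#' @param allow_leakage Permit `aq_day_offset = 0` (see above).
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(target_pollutant = c("pm25", "co"),
                        feature_set = c("all", "target_only", "pol", "meo"),
                        include_weekly_channel = TRUE,
                        aq_day_offset = -1L,
                        meo_day_offset = -1L,
                        weekly_day_offset = -7L,
                        allow_leakage = FALSE) {
  target_pollutant <- match.arg(target_pollutant)
  feature_set <- match.arg(feature_set)
  if (weekly_day_offset >= 0)
    stop("day offsets must be negative", call. = FALSE)
  if (meo_day_offset > 0)
    stop("meo_day_offset must be <= 0 (0 = forecast-day meteorology)",
         call. = FALSE)
  if (aq_day_offset >= 0 && !(aq_day_offset == 0 && allow_leakage))
    stop("aq_day_offset must be negative (offset 0 leaks the target; ",
         "set allow_leakage = TRUE to force it)", call. = FALSE)
  structure(
    list(target_pollutant = target_pollutant, feature_set = feature_set,
         include_weekly_channel = isTRUE(include_weekly_channel),
         aq_day_offset = as.integer(aq_day_offset),
         meo_day_offset = as.integer(meo_day_offset),
         weekly_day_offset = as.integer(weekly_day_offset),
         input_length = 24L, output_length = 24L),
    class = "window_spec"
  )
}

## (channel, day-offset) table defining the feature columns, in order
window_feature_table <- function(spec) {
  aq <- switch(spec$feature_set,
    target_only = c("pm25", "co"),
    pol = pollutant_channels(),
    meo = c("pm25", "co"),
    all = pollutant_channels()
  )
  tab <- data.frame(channel = aq, offset = spec$aq_day_offset,
                    stringsAsFactors = FALSE)
  if (spec$feature_set %in% c("meo", "all"))
    tab <- rbind(tab, data.frame(channel = meo_feature_channels(),
                                 offset = spec$meo_day_offset))
  if (spec$include_weekly_channel)
    tab <- rbind(tab, data.frame(channel = spec$target_pollutant,
                                 offset = spec$weekly_day_offset))
  tab$name <- sprintf("%s_t%d", tab$channel, tab$offset)
  tab
}

#' Number of input features implied by a window spec
#' @param spec A [window_spec()].
#' @return Integer F.
#' @export
n_features <- function(spec) nrow(window_feature_table(spec))

#' Assemble forecast-day samples from a station series
#'
#' Emits one sample per forecast day T for which day T and every referenced
#' offset day are complete (24 hours present) and gap-free in the channels
#' the sample uses. Windows touching unresolved gaps are dropped whole — no
#' partial targets. Features and targets are scaled with the supplied
#' (train-fitted) scaler; the raw target values are kept alongside for
#' evaluation in original units.
#'
#' The week-ago anchor day (target pollutant at `weekly_day_offset`) is
#' required to be present and gap-free even when `include_weekly_channel` is
#' off: this keeps the emitted forecast days identical across model variants
#' with and without the weekly channel, so their test sets are directly
#' comparable.
#'
#' @param series A [station_series()], normally after [impute_missing()].
#' @param spec A [window_spec()].
#' @param scaler A fitted [fit_scaler()] object.
#' @return List of `sample_window` objects, each with fields `x` (24 x F
#'   scaled matrix, columns named with lag provenance like `pm25_t-7`), `y`
#'   (24 scaled targets), `y_raw` (original units), `target_date`,
#'   `feature_channels` (base channel of each column).
#' @export
build_samples <- function(series, spec, scaler) {
  if (!inherits(spec, "window_spec")) stop("spec must be a window_spec", call. = FALSE)
  check_scaler(scaler)
  dates <- series_date(series$time)
  day_rows <- split(seq_along(series$time), dates)
  complete <- vapply(day_rows, function(ix) length(ix) == 24L, logical(1))
  day_rows <- day_rows[complete]
  if (length(day_rows) < 8L)
    stop("series must contain at least 8 complete days", call. = FALSE)
  day_dates <- as.Date(names(day_rows))
  tab <- window_feature_table(spec)
  tgt <- spec$target_pollutant
  # gating table: the weekly anchor is required even when its channel is off
  gate <- tab[c("channel", "offset")]
  if (!spec$include_weekly_channel)
    gate <- rbind(gate, data.frame(channel = tgt,
                                   offset = spec$weekly_day_offset))
  offsets <- sort(unique(gate$offset))

  samples <- list()
  for (d in seq_along(day_dates)) {
    T_date <- day_dates[d]
    need <- as.character(T_date + offsets)
    if (!all(need %in% names(day_rows))) next
    y_raw <- series$data[[tgt]][day_rows[[as.character(T_date)]]]
    if (anyNA(y_raw)) next
    ok <- TRUE
    for (j in seq_len(nrow(gate))) {
      rows <- day_rows[[as.character(T_date + gate$offset[j])]]
      if (anyNA(series$data[[gate$channel[j]]][rows])) { ok <- FALSE; break }
    }
    if (!ok) next
    x <- matrix(NA_real_, 24L, nrow(tab),
                dimnames = list(NULL, tab$name))
    for (j in seq_len(nrow(tab))) {
      rows <- day_rows[[as.character(T_date + tab$offset[j])]]
      x[, j] <- series$data[[tab$channel[j]]][rows]
    }
    x <- apply_scaler(scaler, x, tab$channel, inverse = FALSE)
    samples[[length(samples) + 1L]] <- structure(
      list(x = x, y = scale_values(scaler, y_raw, tgt), y_raw = y_raw,
           target_date = T_date, feature_channels = tab$channel),
      class = "sample_window"
    )
  }
  samples
}

## stack a sample list into time-major arrays for the batched network code:
## X = list of 24 matrices (N x F), Y and Y_raw = N x 24 matrices
stack_samples <- function(samples) {
  N <- length(samples)
  F_ <- ncol(samples[[1]]$x)
  X <- lapply(1:24, function(t)
    matrix(vapply(samples, function(s) s$x[t, ], numeric(F_)),
           nrow = N, ncol = F_, byrow = TRUE))
  Y <- t(vapply(samples, function(s) s$y, numeric(24)))
  Y_raw <- t(vapply(samples, function(s) s$y_raw, numeric(24)))
  list(X = X, Y = Y, Y_raw = Y_raw, N = N, F = F_)
}
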