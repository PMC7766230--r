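## Station CSV input/output, gap imputation, chronological splitting.
##
## CSV contract: header
##   timestamp,pm25,pm10,co,no2,o3,so2,temp,rh,pressure,wind_speed,wind_dir,precip
## one row per hour, timestamps `YYYY-MM-DD HH:00` in timezone-naive local
## time, empty string = missing, UTF-8, comma-separated.

csv_header <- function() c("timestamp", all_channels())

#' Write a station series to CSV
#'
#' Values are written at full double precision so that
#' [read_station_csv()] round-trips both values and the missing mask
#' exactly; missing cells become empty strings.
#'
#' @param series A [station_series()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_station_csv <- function(series, path) {
  fmt <- function(v) ifelse(is.na(v), "", formatC(v, digits = 17, format = "g"))
  cols <- c(list(format(series$time, "%Y-%m-%d %H:00", tz = "UTC")),
            lapply(series$data, fmt))
  lines <- c(paste(csv_header(), collapse = ","),
             do.call(paste, c(cols, sep = ",")))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a station series from CSV
#'
#' Enforces the CSV contract strictly: a malformed header, non-monotone or
#' duplicated or non-hourly timestamps, or an unparseable numeric cell raise
#' a format error naming the offending row.
#'
#' @param path CSV file path.
#' @param station_id Identifier for the returned series; defaults to the file
#'   name without extension.
#' @return A [station_series()] with missing cells as `NA`.
#' @export
read_station_csv <- function(path, station_id = NULL) {
  if (is.null(station_id))
    station_id <- sub("\\.[^.]*$", "", basename(path))
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = NULL, fileEncoding = "UTF-8")
  if (!identical(names(raw), csv_header()))
    stop("format error: malformed header; expected '",
         paste(csv_header(), collapse = ","), "'", call. = FALSE)
  time <- as.POSIXct(raw$timestamp, format = "%Y-%m-%d %H:%M", tz = "UTC")
  bad <- which(is.na(time))
  if (length(bad))
    stop("format error: unparseable timestamp at row ", bad[1] + 1L, call. = FALSE)
  if (length(time) > 1L) {
    steps <- as.numeric(diff(time), units = "hours")
    dup <- which(steps == 0)
    if (length(dup))
      stop("format error: duplicated timestamp '",
           format(time[dup[1] + 1L], "%Y-%m-%d %H:00"), "' at row ",
           dup[1] + 2L, call. = FALSE)
    if (any(steps < 0))
      stop("format error: non-monotone timestamps at row ",
           which(steps < 0)[1] + 2L, call. = FALSE)
    if (any(steps != 1))
      stop("format error: non-hourly timestamp step at row ",
           which(steps != 1)[1] + 2L, call. = FALSE)
  }
  data <- lapply(all_channels(), function(ch) {
    v <- raw[[ch]]
    out <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(out) & v != "")
    if (length(bad))
      stop("format error: unparseable value '", v[bad[1]], "' in column '",
           ch, "' at row ", bad[1] + 1L, call. = FALSE)
    out
  })
  names(data) <- all_channels()
  station_series(station_id, time, as.data.frame(data))
}

#' Linearly impute short gaps
#'
#' Interior runs of missing values of length at most `max_gap_hours` are
#' filled by per-channel linear interpolation between the bracketing observed
#' values; longer gaps and gaps touching a series end are left missing.
#' Observed values are never altered.
#'
#' @param series A [station_series()].
#' @param max_gap_hours Maximum gap length to fill (>= 0; 0 is the identity).
#' @return The imputed [station_series()].
#' @export
impute_missing <- function(series, max_gap_hours) {
  if (max_gap_hours < 0) stop("max_gap_hours must be >= 0", call. = FALSE)
  if (max_gap_hours == 0) return(series)
  data <- series$data
  n <- nrow(data)
  for (ch in names(data)) {
    v <- data[[ch]]
    r <- rle(is.na(v))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      if (r$lengths[j] > max_gap_hours) next
      lo <- starts[j] - 1L; hi <- ends[j] + 1L
      if (lo < 1L || hi > n) next      # edge gap: no bracketing observation
      idx <- starts[j]:ends[j]
      w <- (idx - lo) / (hi - lo)
      v[idx] <- (1 - w) * v[lo] + w * v[hi]
    }
    data[[ch]] <- v
  }
  station_series(series$station_id, series$time, data)
}

#' Chronological split specification
#'
#' @param train,val,test Strictly positive fractions summing to 1.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(train = 0.7, val = 0.15, test = 0.15) {
  if (any(c(train, val, test) <= 0))
    stop("split fractions must be strictly positive", call. = FALSE)
  if (abs(train + val + test - 1) > 1e-9)
    stop("split fractions must sum to 1", call. = FALSE)
  structure(list(train = train, val = val, test = test), class = "split_spec")
}

#' Split a series chronologically at day boundaries
#'
#' Produces a contiguous, day-aligned, disjoint and exhaustive partition into
#' train / validation / test sub-series, in time order. Day counts are the
#' rounded cumulative fractions, so each boundary is within one day of the
#' exact fraction.
#'
#' @param series A [station_series()] spanning at least 30 days.
#' @param spec A [split_spec()].
#' @return Named list of three [station_series()]: `train`, `val`, `test`.
#' @export
split_series <- function(series, spec = split_spec()) {
  if (!inherits(spec, "split_spec")) stop("spec must be a split_spec", call. = FALSE)
  dates <- series_date(series$time)
  days <- unique(dates)
  D <- length(days)
  if (D < 30) stop("series must span at least 30 days", call. = FALSE)
  b1 <- round(spec$train * D)
  b2 <- round((spec$train + spec$val) * D)
  if (b1 < 1 || b2 <= b1 || b2 >= D)
    stop("split fractions leave an empty partition", call. = FALSE)
  part <- findInterval(match(dates, days), c(b1, b2) + 0.5) + 1L
  list(train = subset_series(series, part == 1L),
       val   = subset_series(series, part == 2L),
       test  = subset_series(series, part == 3L))
}
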