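## Per-channel affine feature scaling, fitted on the training split only.

#' Fit a per-channel scaler on training data
#'
#' Fits an affine transform per channel on the non-missing values of the
#' training series: min-max (`(x - min) / (max - min)`, the default) or
#' z-score (`(x - mean) / sd`). Constant channels get unit scale so the
#' transform stays invertible.
#'
#' @param train A [station_series()] — the training split; fitting on
#'   anything later leaks information into evaluation.
#' @param method `"minmax"` or `"zscore"`.
#' @return An object of class `channel_scaler`.
#' @export
fit_scaler <- function(train, method = c("minmax", "zscore")) {
  method <- match.arg(method)
  params <- lapply(train$data, function(v) {
    v <- v[!is.na(v)]
    if (!length(v)) return(c(center = 0, scale = 1))
    if (method == "minmax") {
      rng <- range(v)
      c(center = rng[1], scale = if (diff(rng) > 0) diff(rng) else 1)
    } else {
      s <- stats::sd(v)
      c(center = mean(v), scale = if (isTRUE(s > 0)) s else 1)
    }
  })
  structure(list(method = method, params = params), class = "channel_scaler")
}

check_scaler <- function(scaler) {
  if (!inherits(scaler, "channel_scaler"))
    stop("scaler has not been fitted (expected a channel_scaler)", call. = FALSE)
}

#' Apply or invert a fitted scaler
#'
#' `scale_values()` maps raw values to scaled space; `unscale_values()` is
#' its exact inverse (`unscale(scale(x)) == x` to machine precision).
#' `x` may be a vector (with `channel` given) or a matrix whose column names
#' are channel names.
#'
#' @param scaler A fitted [fit_scaler()] object.
#' @param x Numeric vector or matrix.
#' @param channel Channel name for vector input, or a vector of channel names
#'   overriding matrix column names.
#' @return Object of the same shape as `x`.
#' @export
scale_values <- function(scaler, x, channel = NULL) {
  apply_scaler(scaler, x, channel, inverse = FALSE)
}

#' @rdname scale_values
#' @export
unscale_values <- function(scaler, x, channel = NULL) {
  apply_scaler(scaler, x, channel, inverse = TRUE)
}

apply_scaler <- function(scaler, x, channel, inverse) {
  check_scaler(scaler)
  one <- function(v, ch) {
    p <- scaler$params[[ch]]
    if (is.null(p)) stop("scaler has no channel '", ch, "'", call. = FALSE)
    if (inverse) v * p[["scale"]] + p[["center"]]
    else (v - p[["center"]]) / p[["scale"]]
  }
  if (is.matrix(x)) {
    chs <- if (is.null(channel)) colnames(x) else channel
    if (is.null(chs)) stop("matrix input needs column names or 'channel'", call. = FALSE)
    for (j in seq_len(ncol(x))) x[, j] <- one(x[, j], chs[j])
    x
  } else {
    if (is.null(channel) || length(channel) != 1L)
      stop("vector input needs a single 'channel'", call. = FALSE)
    one(x, channel)
  }
}
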