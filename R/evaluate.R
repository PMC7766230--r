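## Forecast metrics and the model-comparison / input-ablation protocols.

check_pair <- function(O, P) {
  if (length(O) != length(P))
    stop("argument error: O and P lengths differ", call. = FALSE)
  if (length(O) < 1L) stop("argument error: empty vectors", call. = FALSE)
  if (any(!is.finite(O)) || any(!is.finite(P)))
    stop("argument error: non-finite values", call. = FALSE)
}

#' Forecast error metrics
#'
#' The three standard indices for observed `O` and predicted `P`:
#' \itemize{
#'   \item `rmse`: \eqn{\sqrt{\frac{1}{n}\sum_i (O_i - P_i)^2}} (concentration
#'     units);
#'   \item `nmse`: \eqn{\overline{(P_i - O_i)^2} / (\bar P \cdot \bar O)},
#'     the mean squared error normalised by the product of the two means
#'     (dimensionless, scale-invariant, requires positive means);
#'   \item `pearson_r`: the product-moment correlation coefficient.
#' }
#'
#' @param O Observed values.
#' @param P Predicted values.
#' @return A single numeric value.
#' @export
rmse <- function(O, P) {
  check_pair(O, P)
  sqrt(mean((O - P)^2))
}

#' @rdname rmse
#' @export
nmse <- function(O, P) {
  check_pair(O, P)
  denom <- mean(P) * mean(O)
  if (denom <= 0)
    stop("degenerate denominator: mean(P) * mean(O) must be positive",
         call. = FALSE)
  mean((P - O)^2) / denom
}

#' @rdname rmse
#' @export
pearson_r <- function(O, P) {
  check_pair(O, P)
  if (length(O) < 2L) stop("argument error: need at least 2 pairs", call. = FALSE)
  dO <- O - mean(O); dP <- P - mean(P)
  sO <- sum(dO^2); sP <- sum(dP^2)
  if (sO == 0 || sP == 0)
    stop("degenerate variance: constant input", call. = FALSE)
  sum(dO * dP) / sqrt(sO * sP)
}

#' All three metrics as a report
#'
#' @inheritParams rmse
#' @param pooling Label recording the pooling convention (all test hours
#'   pooled, by default).
#' @return List with `rmse`, `nmse`, `pearson_r`, `n`, `pooling`.
#' @export
metrics_report <- function(O, P, pooling = "pooled_hours") {
  list(rmse = rmse(O, P), nmse = nmse(O, P), pearson_r = pearson_r(O, P),
       n = length(O), pooling = pooling)
}

## ---------------------------------------------------------------------------

#' Run one end-to-end forecasting experiment
#'
#' The full pipeline on a single station: impute short gaps, split
#' chronologically, fit the scaler on the training period only, assemble
#' samples over the whole record assigned to splits by forecast date (inputs
#' may reach back across a boundary, which is causal and leakage-free),
#' train the requested variant, and evaluate on the test days with all test
#' hours pooled.
#'
#' @param series A [station_series()].
#' @param target Target pollutant, `"pm25"` or `"co"`.
#' @param variant Model variant, see [build_variant()].
#' @param cfg A [train_config()]; its seed also seeds parameter
#'   initialisation.
#' @param feature_set Input feature set, see [window_spec()].
#' @param hidden_size Hidden dimension.
#' @param split A [split_spec()].
#' @param max_gap_hours Imputation threshold.
#' @param scaler_method `"minmax"` or `"zscore"`.
#' @param context_rule See [build_variant()].
#' @param meo_day_offset Day offset of the meteorology block (see
#'   [window_spec()]); 0 emulates forecast-day (WRF-style) meteorology.
#' @return List: `metrics` ([metrics_report()]), `model`, `history`,
#'   `n_test`, `predictions` and `observed` (test matrices, original units).
#' @export
run_experiment <- function(series, target, variant = "seq2seq_weekly",
                           cfg = train_config(), feature_set = "all",
                           hidden_size = 64L, split = split_spec(),
                           max_gap_hours = 3L, scaler_method = "minmax",
                           context_rule = "last", meo_day_offset = -1L) {
  series <- impute_missing(series, max_gap_hours)
  parts <- split_series(series, split)
  scaler <- fit_scaler(parts$train, scaler_method)
  spec <- window_spec(target_pollutant = target, feature_set = feature_set,
                      include_weekly_channel = variant == "seq2seq_weekly",
                      meo_day_offset = meo_day_offset)
  all_samples <- build_samples(series, spec, scaler)
  last_train <- max(series_date(parts$train$time))
  last_val <- max(series_date(parts$val$time))
  dts <- as.Date(vapply(all_samples, function(s) as.character(s$target_date), ""))
  tr <- all_samples[dts <= last_train]
  va <- all_samples[dts > last_train & dts <= last_val]
  te <- all_samples[dts > last_val]
  if (length(te) < 1L) stop("no test samples survive gap filtering", call. = FALSE)
  model <- build_variant(variant, spec, hidden_size = hidden_size,
                         context_rule = context_rule, seed = cfg$seed)
  model <- train_model(model, tr, cfg, val_samples = va)
  P <- predict_model(model, te, scaler)
  O <- t(vapply(te, function(s) s$y_raw, numeric(24)))
  list(metrics = metrics_report(as.numeric(O), as.numeric(P)),
       model = model, history = model$history, n_test = length(te),
       predictions = P, observed = O)
}

#' Compare model variants over multiple seeds
#'
#' The model-comparison protocol: for each target pollutant and variant,
#' train with `n_seeds` different seeds and evaluate pooled over all test
#' hours. Stochastic model orderings are only meaningful across seeds, so
#' per-seed rows are returned and [summarize_comparison()] reduces them to
#' medians.
#'
#' @param series A [station_series()].
#' @param targets Target pollutants.
#' @param variants Model variants.
#' @param cfg Base [train_config()]; seed `cfg$seed + k - 1` is used for run
#'   `k`.
#' @param n_seeds Number of seeds per cell.
#' @param ... Passed to [run_experiment()].
#' @return A `comparison_table` data frame with one row per (target,
#'   variant, seed); failed runs carry `NA` metrics and the error message.
#' @export
compare_models <- function(series, targets = c("pm25", "co"),
                           variants = c("seq2seq_weekly", "seq2seq",
                                        "bilstm", "lstm"),
                           cfg = train_config(), n_seeds = 5L, ...) {
  if (!length(variants)) stop("variants must be non-empty", call. = FALSE)
  rows <- list()
  for (target in targets) for (variant in variants) for (k in seq_len(n_seeds)) {
    cfg_k <- cfg; cfg_k$seed <- cfg$seed + k - 1L
    res <- tryCatch(
      run_experiment(series, target, variant, cfg = cfg_k, ...),
      error = function(e) e)
    rows[[length(rows) + 1L]] <- if (inherits(res, "error")) {
      data.frame(station = series$station_id, target = target,
                 variant = variant, seed = cfg_k$seed, rmse = NA_real_,
                 nmse = NA_real_, r = NA_real_, n = NA_integer_,
                 note = conditionMessage(res))
    } else {
      data.frame(station = series$station_id, target = target,
                 variant = variant, seed = cfg_k$seed,
                 rmse = res$metrics$rmse, nmse = res$metrics$nmse,
                 r = res$metrics$pearson_r, n = res$metrics$n, note = "")
    }
  }
  structure(do.call(rbind, rows), class = c("comparison_table", "data.frame"))
}

#' Median metrics per comparison cell
#'
#' @param tbl A [compare_models()] or [ablation()] table.
#' @return Data frame of median `rmse`, `nmse`, `r` per grouping key.
#' @export
summarize_comparison <- function(tbl) {
  key_cols <- intersect(c("station", "target", "variant", "feature_set"),
                        names(tbl))
  keys <- tbl[key_cols]
  agg <- stats::aggregate(tbl[c("rmse", "nmse", "r")], by = keys,
                          FUN = stats::median, na.rm = TRUE)
  agg[do.call(order, agg[key_cols]), , drop = FALSE]
}

#' Input-ablation protocol
#'
#' Trains the proposed variant (`seq2seq_weekly`) under each input feature
#' set, multi-seed, to quantify what the auxiliary pollutants and the
#' meteorology contribute.
#'
#' @inheritParams compare_models
#' @param target Single target pollutant.
#' @param feature_sets Feature sets to compare, see [window_spec()].
#' @return A `comparison_table` data frame with a `feature_set` column.
#' @export
ablation <- function(series, target = "pm25",
                     feature_sets = c("target_only", "pol", "meo", "all"),
                     cfg = train_config(), n_seeds = 5L, ...) {
  rows <- list()
  for (fs in feature_sets) for (k in seq_len(n_seeds)) {
    cfg_k <- cfg; cfg_k$seed <- cfg$seed + k - 1L
    res <- tryCatch(
      run_experiment(series, target, "seq2seq_weekly", cfg = cfg_k,
                     feature_set = fs, ...),
      error = function(e) e)
    rows[[length(rows) + 1L]] <- if (inherits(res, "error")) {
      data.frame(station = series$station_id, target = target,
                 feature_set = fs, seed = cfg_k$seed, rmse = NA_real_,
                 nmse = NA_real_, r = NA_real_, n = NA_integer_,
                 note = conditionMessage(res))
    } else {
      data.frame(station = series$station_id, target = target,
                 feature_set = fs, seed = cfg_k$seed,
                 rmse = res$metrics$rmse, nmse = res$metrics$nmse,
                 r = res$metrics$pearson_r, n = res$metrics$n, note = "")
    }
  }
  structure(do.call(rbind, rows), class = c("comparison_table", "data.frame"))
}
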