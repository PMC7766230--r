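# Shared fixtures, all generated in code.

# zero coupling for every pollutant: isolates the deterministic diurnal /
# weekly structure from the meteorology
zero_coupling <- function() {
  stats::setNames(rep(list(numeric(0)), 6), pollutant_channels())
}

# noise-free, gap-free, meteorology-decoupled generator config
clean_config <- function(n_days = 30, seed = 1, ...) {
  synth_config(n_days = n_days, noise_sd = 0, missing_rate = 0,
               meteo_coupling = zero_coupling(), seed = seed, ...)
}

# a series whose every channel is the given function of (hour, dow);
# defaults to constant 1
toy_series <- function(n_days, fn = function(hour, dow) rep(1, length(hour)),
                       start_date = "2015-03-02") {
  time <- as.POSIXct(paste(start_date, "00:00:00"), tz = "UTC") +
    3600 * (seq_len(n_days * 24) - 1)
  hour <- as.POSIXlt(time, tz = "UTC")$hour
  dow <- (as.POSIXlt(time, tz = "UTC")$wday + 6L) %% 7L + 1L
  v <- fn(hour, dow)
  data <- as.data.frame(stats::setNames(
    rep(list(v), 12), c(pollutant_channels(), meteo_channels())))
  station_series("TOY", time, data)
}

# brute-force double-loop autocorrelation (biased, single global mean)
acf_oracle <- function(y, max_lag) {
  T_ <- length(y)
  ybar <- mean(y)
  c_k <- numeric(max_lag + 1)
  for (k in 0:max_lag) {
    s <- 0
    for (t in 1:(T_ - k)) s <- s + (y[t] - ybar) * (y[t + k] - ybar)
    c_k[k + 1] <- s / T_
  }
  c_k / c_k[1]
}

# scalar-loop LSTM cell oracle: literal componentwise evaluation of the
# gated recurrence, no matrix ops
lstm_cell_oracle <- function(p, x, h_prev, c_prev) {
  H <- p$hidden_size; F_ <- p$input_size
  sig <- function(z) 1 / (1 + exp(-z))
  h_new <- numeric(H); c_new <- numeric(H)
  for (j in 1:H) {
    ai <- p$bi[j]; af <- p$bf[j]; ao <- p$bo[j]; ac <- p$bc[j]
    for (k in 1:F_) {
      ai <- ai + p$Wi[k, j] * x[k]; af <- af + p$Wf[k, j] * x[k]
      ao <- ao + p$Wo[k, j] * x[k]; ac <- ac + p$Wc[k, j] * x[k]
    }
    for (k in 1:H) {
      ai <- ai + p$Ui[k, j] * h_prev[k]; af <- af + p$Uf[k, j] * h_prev[k]
      ao <- ao + p$Uo[k, j] * h_prev[k]; ac <- ac + p$Uc[k, j] * h_prev[k]
    }
    i <- sig(ai); f <- sig(af); o <- sig(ao); g <- tanh(ac)
    c_new[j] <- f * c_prev[j] + i * g
    h_new[j] <- o * tanh(c_new[j])
  }
  list(h = h_new, c = c_new)
}

# all-zero LSTM parameters of the given shape
zero_lstm_params <- function(input_size, hidden_size) {
  p <- lstm_params(input_size, hidden_size)
  for (f in c("Wi", "Wf", "Wo", "Wc", "Ui", "Uf", "Uo", "Uc"))
    p[[f]] <- 0 * p[[f]]
  for (f in c("bi", "bf", "bo", "bc")) p[[f]] <- 0 * p[[f]]
  p
}

# small training setup shared by model tests: noise-free series with a
# diurnal cycle only, quick train config
quick_train_cfg <- function(epochs = 50, seed = 1)
  train_config(epochs = epochs, patience = epochs, seed = seed)
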