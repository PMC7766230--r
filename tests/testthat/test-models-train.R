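train_fixture <- function(n_days = 40, seed = 2, weekly = rep(1, 7)) {
  s <- generate_station(clean_config(n_days = n_days, seed = seed,
                                     weekly_weights = weekly))
  scaler <- fit_scaler(s)
  spec <- window_spec("pm25", "target_only")
  spec_plain <- window_spec("pm25", "target_only",
                            include_weekly_channel = FALSE)
  list(series = s, scaler = scaler, spec = spec, spec_plain = spec_plain,
       samples = build_samples(s, spec, scaler),
       samples_plain = build_samples(s, spec_plain, scaler))
}

test_that("training fits constant targets to near zero error quickly", {
  fx <- train_fixture()
  # constant series: every scaled target is identical
  const <- lapply(fx$samples, function(s) { s$y[] <- 0.5; s })
  model <- build_variant("seq2seq_weekly", fx$spec, hidden_size = 8, seed = 1)
  model <- train_model(model, const, quick_train_cfg(epochs = 50))
  expect_lt(sqrt(min(model$history$train_loss)), 0.05)
})

test_that("loss history is reproducible and bounded by the epoch budget", {
  fx <- train_fixture()
  cfg <- train_config(epochs = 12, patience = 4, seed = 9)
  m1 <- train_model(build_variant("seq2seq_weekly", fx$spec, 8, seed = 9),
                    fx$samples, cfg)
  m2 <- train_model(build_variant("seq2seq_weekly", fx$spec, 8, seed = 9),
                    fx$samples, cfg)
  expect_identical(m1$history, m2$history)
  expect_lte(nrow(m1$history), 12)
  expect_lt(min(m1$history$train_loss), m1$history$train_loss[1])
  expect_error(train_model(m1, fx$samples[0], cfg), "at least 2")
})

test_that("early stopping halts on a stalled validation loss", {
  fx <- train_fixture(n_days = 45)
  # constant targets: the loss bottoms out, so patience must trigger
  const <- lapply(fx$samples_plain, function(s) { s$y[] <- 0.5; s })
  n <- length(const)
  cfg <- train_config(epochs = 100, patience = 3, seed = 4)
  model <- train_model(build_variant("lstm", fx$spec_plain, 4, seed = 4),
                       const[1:(n - 5)], cfg,
                       val_samples = const[(n - 4):n])
  expect_lt(nrow(model$history), 100)
  expect_false(any(is.na(model$history$val_loss)))
})

test_that("predictions invert the scaler and beat the mean predictor on periodic data", {
  s <- generate_station(clean_config(n_days = 120, seed = 3,
                                     weekly_weights = c(1, .85, .9, 1.05, 1.25, 1, 1.15)))
  res <- run_experiment(s, "pm25", "seq2seq_weekly",
                        cfg = train_config(epochs = 60, patience = 15, seed = 1),
                        feature_set = "target_only", hidden_size = 16)
  expect_length(res$predictions[1, ], 24)
  expect_true(all(is.finite(res$predictions)))
  # noise-free periodic signal: learned model must beat the mean predictor
  expect_lt(res$metrics$rmse, sd(res$observed))
  # inverse-scaling contract
  te_sample <- structure(list(x = matrix(0.5, 24,
                                         res$model$input_size), y = rep(0.5, 24),
                              y_raw = rep(1, 24), target_date = Sys.Date(),
                              feature_channels = NULL),
                         class = "sample_window")
  scaler <- fit_scaler(s)
  p <- predict_model(res$model, te_sample, scaler)
  st <- roadcast:::stack_samples(list(te_sample))
  raw <- roadcast:::model_loss_grads(res$model, st$X, matrix(0, 1, 24),
                                     grads = FALSE)$yhat
  expect_equal(p, unscale_values(scaler, drop(raw), "pm25"), tolerance = 1e-12)
  expect_error(predict_model(res$model, te_sample, NULL), "not been fitted")
})

test_that("teacher forcing is never used at inference", {
  fx <- train_fixture()
  model <- build_variant("seq2seq", fx$spec_plain, 6, seed = 2)
  model <- train_model(model, fx$samples_plain, quick_train_cfg(epochs = 3))
  # predictions are a deterministic function of the input alone
  p1 <- predict_model(model, fx$samples_plain[[1]], fx$scaler)
  set.seed(999)  # RNG state must not matter
  p2 <- predict_model(model, fx$samples_plain[[1]], fx$scaler)
  expect_identical(p1, p2)
  # and equal the explicit encode -> decode composition
  ctx <- encode(model, fx$samples_plain[[1]]$x)
  expect_equal(unscale_values(fx$scaler, decode(model, ctx), "pm25"), p1,
               tolerance = 1e-12)
})
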