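test_that("metric worked example evaluates by hand", {
  O <- c(1, 2, 3, 4); P <- c(2, 3, 4, 5)
  expect_equal(rmse(O, P), 1.0, tolerance = 1e-12)
  expect_equal(nmse(O, P), 1 / (3.5 * 2.5), tolerance = 1e-12)
  expect_equal(pearson_r(O, P), 1.0, tolerance = 1e-12)
})

test_that("metrics agree with brute-force loop oracles on random pairs", {
  set.seed(13)
  loop_rmse <- function(O, P) {
    s <- 0; for (i in seq_along(O)) s <- s + (O[i] - P[i])^2
    sqrt(s / length(O))
  }
  loop_nmse <- function(O, P) {
    s <- 0; for (i in seq_along(O)) s <- s + (P[i] - O[i])^2
    (s / length(O)) / (mean(P) * mean(O))
  }
  loop_r <- function(O, P) {
    n <- length(O); num <- 0; dO <- 0; dP <- 0
    for (i in 1:n) {
      num <- num + (O[i] - mean(O)) * (P[i] - mean(P))
      dO <- dO + (O[i] - mean(O))^2
      dP <- dP + (P[i] - mean(P))^2
    }
    num / sqrt(dO * dP)
  }
  worst <- 0
  for (rep in 1:100) {
    n <- sample(2:40, 1)
    O <- runif(n, 1, 100); P <- runif(n, 1, 100)
    worst <- max(worst,
                 abs(rmse(O, P) - loop_rmse(O, P)),
                 abs(nmse(O, P) - loop_nmse(O, P)),
                 abs(pearson_r(O, P) - loop_r(O, P)))
  }
  expect_lt(worst, 1e-12)
  # cross-check r against the standard library implementation
  O <- runif(50, 1, 9); P <- O * 1.4 + rnorm(50)
  expect_equal(pearson_r(O, P), cor(O, P), tolerance = 1e-12)
})

test_that("rmse is homogeneous and nmse scale-invariant", {
  set.seed(17)
  O <- runif(30, 5, 50); P <- runif(30, 5, 50)
  for (alpha in runif(5, 0.01, 10)) {
    expect_equal(rmse(alpha * O, alpha * P), alpha * rmse(O, P),
                 tolerance = 1e-12)
    expect_equal(nmse(alpha * O, alpha * P), nmse(O, P), tolerance = 1e-12)
  }
  expect_equal(pearson_r(O, 2 * O + 3), 1.0, tolerance = 1e-12)
  expect_equal(pearson_r(O, -O), -1.0, tolerance = 1e-12)
})

test_that("degenerate metric inputs raise the documented errors", {
  expect_error(rmse(1:3, 1:4), "lengths differ")
  expect_error(nmse(c(1, -2), c(1, 1)), "denominator")
  expect_error(pearson_r(rep(2, 5), 1:5), "degenerate")
  expect_error(rmse(c(1, NA), c(1, 2)), "non-finite")
})

test_that("pooled metrics equal metrics on the concatenated vectors", {
  set.seed(19)
  days <- lapply(1:6, function(i) list(O = runif(24, 10, 60),
                                       P = runif(24, 10, 60)))
  O_all <- unlist(lapply(days, `[[`, "O"))
  P_all <- unlist(lapply(days, `[[`, "P"))
  rep_pooled <- metrics_report(O_all, P_all)
  expect_identical(rep_pooled$n, 144L)
  expect_equal(rep_pooled$rmse,
               sqrt(mean(unlist(lapply(days, function(d) (d$O - d$P)^2)))),
               tolerance = 1e-12)
})

test_that("a single comparison cell equals the direct experiment", {
  s <- generate_station(synth_config(n_days = 60, seed = 6, missing_rate = 0.01))
  cfg <- train_config(epochs = 5, patience = 5, seed = 31)
  tbl <- compare_models(s, targets = "co", variants = "lstm", cfg = cfg,
                        n_seeds = 1, hidden_size = 6)
  expect_s3_class(tbl, "comparison_table")
  direct <- run_experiment(s, "co", "lstm", cfg = cfg, hidden_size = 6)
  expect_equal(tbl$rmse, direct$metrics$rmse, tolerance = 1e-12)
  expect_equal(tbl$nmse, direct$metrics$nmse, tolerance = 1e-12)
  expect_equal(tbl$r, direct$metrics$pearson_r, tolerance = 1e-12)
  # table round-trips through CSV
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(tbl, path, row.names = FALSE)
  back <- utils::read.csv(path)
  expect_equal(back$rmse, tbl$rmse, tolerance = 1e-12)
  expect_identical(back$variant, tbl$variant)
  # summary collapses seeds to medians
  summ <- summarize_comparison(tbl)
  expect_identical(nrow(summ), 1L)
  expect_equal(summ$rmse, tbl$rmse)
})

test_that("failed cells are recorded without aborting the table", {
  s <- generate_station(synth_config(n_days = 60, seed = 6))
  cfg <- train_config(epochs = 2, patience = 2, seed = 1)
  # a split the series cannot support fails per-cell
  tbl <- compare_models(s, targets = "pm25", variants = "lstm", cfg = cfg,
                        n_seeds = 1, hidden_size = 4,
                        split = split_spec(0.98, 0.01, 0.01))
  expect_identical(nrow(tbl), 1L)
  expect_true(is.na(tbl$rmse))
  expect_match(tbl$note, ".+")
})
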