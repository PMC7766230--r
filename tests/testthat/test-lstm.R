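test_that("zero parameters give zero cell and hidden state", {
  p <- zero_lstm_params(3, 4)
  st <- lstm_cell_step(p, c(1, -2, 0.5))
  expect_equal(st$h, rep(0, 4))
  expect_equal(st$c, rep(0, 4))
})

test_that("the scalar all-ones step matches the hand evaluation", {
  p <- zero_lstm_params(1, 1)
  for (f in c("Wi", "Wf", "Wo", "Wc", "Ui", "Uf", "Uo", "Uc"))
    p[[f]] <- matrix(1)
  st <- lstm_cell_step(p, 1, list(h = 0, c = 0))
  sig1 <- plogis(1)
  c_expect <- sig1 * tanh(1)            # ~0.5568
  h_expect <- sig1 * tanh(c_expect)     # ~0.3696
  expect_equal(st$c, c_expect, tolerance = 1e-12)
  expect_equal(st$h, h_expect, tolerance = 1e-12)
  expect_equal(round(c_expect, 4), 0.5568)
  expect_equal(round(h_expect, 4), 0.3696)
})

test_that("the vectorised cell agrees with a scalar-loop oracle", {
  set.seed(21)
  worst <- 0
  for (rep in 1:100) {
    F_ <- sample(1:5, 1); H <- sample(1:6, 1)
    p <- lstm_params(F_, H)
    x <- rnorm(F_); h0 <- rnorm(H); c0 <- rnorm(H)
    got <- lstm_cell_step(p, x, list(h = h0, c = c0))
    ref <- lstm_cell_oracle(p, x, h0, c0)
    worst <- max(worst, abs(got$h - ref$h), abs(got$c - ref$c))
  }
  expect_lt(worst, 1e-10)
})

test_that("gates and hidden state respect their analytic bounds", {
  set.seed(31)
  for (rep in 1:20) {
    p <- lstm_params(4, 5)
    st <- list(h = rnorm(5), c = rnorm(5, sd = 3))
    for (t in 1:10) st <- lstm_cell_step(p, rnorm(4, sd = 3), st)
    expect_true(all(abs(st$h) < 1))
  }
})

test_that("shape mismatches are rejected", {
  p <- lstm_params(3, 4)
  expect_error(lstm_cell_step(p, c(1, 2)), "shape error")
  expect_error(lstm_cell_step(p, rnorm(3), list(h = rnorm(2), c = rnorm(2))),
               "shape error")
})

test_that("analytic gradients match finite differences for every variant", {
  spec <- window_spec("pm25", "target_only")
  for (variant in c("seq2seq_weekly", "seq2seq", "bilstm", "lstm")) {
    model <- build_variant(variant, spec, hidden_size = 3, seed = 5)
    set.seed(6)
    B <- 2
    X <- lapply(1:24, function(t) matrix(rnorm(B * model$input_size),
                                         B, model$input_size))
    Y <- matrix(rnorm(B * 24), B, 24)
    # full teacher forcing: fed-back decoder outputs carry no gradient by
    # design, so only the forced path admits a finite-difference comparison
    tf <- rep(TRUE, 24)
    res <- roadcast:::model_loss_grads(model, X, Y, tf_mask = tf)
    tensors <- roadcast:::model_tensors(model)
    eps <- 1e-6
    set.seed(7)
    for (nm in names(tensors)) {
      for (j in sample(seq_along(tensors[[nm]]), min(3, length(tensors[[nm]])))) {
        perturb <- function(d) {
          tt <- tensors; tt[[nm]][j] <- tt[[nm]][j] + d
          m2 <- roadcast:::set_model_tensors(model, tt)
          roadcast:::model_loss_grads(m2, X, Y, tf_mask = tf, grads = FALSE)$loss
        }
        num <- (perturb(eps) - perturb(-eps)) / (2 * eps)
        expect_equal(res$grads[[nm]][j], num, tolerance = 1e-4,
                     label = paste(variant, nm, j))
      }
    }
  }
})

test_that("encode and decode honour their contracts", {
  spec <- window_spec("co", "target_only")
  model <- build_variant("seq2seq", spec, hidden_size = 6, seed = 3)
  x <- matrix(rnorm(24 * model$input_size), 24)
  ctx <- encode(model, x)
  expect_length(ctx$h, 6)
  expect_length(ctx$c, 6)
  # order sensitivity: swapping two input rows changes the context
  x2 <- x[c(2, 1, 3:24), ]
  expect_false(isTRUE(all.equal(encode(model, x2)$h, ctx$h)))
  # decoding yields 24 outputs that depend on the context
  y1 <- decode(model, ctx)
  expect_length(y1, 24)
  y2 <- decode(model, encode(model, x2))
  expect_false(isTRUE(all.equal(y1, y2)))
  expect_error(encode(model, x[, 1, drop = FALSE]), "shape error")

  # zero parameters propagate to a zero context and zero outputs
  zero <- roadcast:::set_model_tensors(
    model, lapply(roadcast:::model_tensors(model), function(x) 0 * x))
  ctx0 <- encode(zero, x)
  expect_equal(ctx0$h, rep(0, 6))
  expect_equal(decode(zero, ctx0), rep(0, 24))

  bl <- build_variant("bilstm", spec, hidden_size = 4, seed = 1)
  expect_error(decode(bl, ctx), "seq2seq variants")
})

test_that("variant architectures account for their parameters", {
  spec <- window_spec("pm25", "all")
  wk <- build_variant("seq2seq_weekly", spec, hidden_size = 8, seed = 1)
  s2s <- build_variant("seq2seq", spec, hidden_size = 8, seed = 1)
  expect_identical(wk$input_size, s2s$input_size + 1L)
  bi <- build_variant("bilstm", spec, hidden_size = 8, seed = 1)
  uni <- build_variant("lstm", spec, hidden_size = 8, seed = 1)
  enc_count <- function(m, blk) sum(vapply(
    roadcast:::model_tensors(m)[grep(paste0("^", blk), names(roadcast:::model_tensors(m)))],
    length, integer(1)))
  expect_identical(enc_count(bi, "(enc|bwd)"), 2L * enc_count(uni, "enc"))
  expect_error(build_variant("gru", spec), "should be one of")
})
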