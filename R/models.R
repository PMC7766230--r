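## Forecasting models: the weekly-periodicity Seq2Seq encoder-decoder, the
## plain Seq2Seq, and the bidirectional-LSTM and LSTM baselines, with
## mean-squared-error training (Adam, backprop through time) on scaled
## targets.

#' Training configuration
#'
#' @param epochs Maximum training epochs.
#' @param batch_size Minibatch size.
#' @param learning_rate Adam step size.
#' @param teacher_forcing_ratio Probability, per decoder step, of feeding the
#'   observed previous target instead of the model's own output during
#'   training (never at inference). In [0, 1].
#' @param patience Early-stopping patience in epochs (on validation loss when
#'   validation samples are supplied, else on training loss).
#' @param min_delta Smallest monitored-loss decrease that counts as an
#'   improvement for early stopping (scaled-MSE units).
#' @param seed Integer seed for shuffling and teacher-forcing draws.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 200L, batch_size = 32L, learning_rate = 3e-3,
                         teacher_forcing_ratio = 0.5, patience = 10L,
                         min_delta = 1e-6, seed = 1L) {
  if (epochs < 1 || batch_size < 1 || patience < 1)
    stop("epochs, batch_size and patience must be positive", call. = FALSE)
  if (learning_rate <= 0) stop("learning_rate must be positive", call. = FALSE)
  if (teacher_forcing_ratio < 0 || teacher_forcing_ratio > 1)
    stop("teacher_forcing_ratio must be in [0, 1]", call. = FALSE)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 teacher_forcing_ratio = teacher_forcing_ratio,
                 patience = as.integer(patience), min_delta = min_delta,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Build a forecasting model variant
#'
#' `seq2seq_weekly` is the proposed model: an LSTM encoder over the 24 x F
#' composite input (including the week-ago target channel) whose final state
#' initialises an autoregressive LSTM decoder emitting 24 hourly values.
#' `seq2seq` is identical without the weekly channel. `bilstm` runs forward
#' and backward LSTM encoders and maps the concatenated final hidden states
#' through a dense layer to all 24 outputs at once; `lstm` does the same
#' with a single direction.
#'
#' @param variant One of `"seq2seq_weekly"`, `"seq2seq"`, `"bilstm"`,
#'   `"lstm"`.
#' @param spec A [window_spec()]; its weekly channel flag is overridden to
#'   match the variant (only `seq2seq_weekly` sees the week-ago channel).
#' @param hidden_size Encoder (and decoder) hidden dimension.
#' @param context_rule How the encoder states become the decoder context:
#'   `"last"` (final hidden and cell state, the default) or `"mean"`
#'   (uniform mean of all encoder hidden states).
#' @param start_value Configured first decoder input, in scaled target space.
#' @param seed Optional seed for parameter initialisation.
#' @return An object of class `seq2seq_model` (all variants share the
#'   class); `n_params` holds the trainable parameter count.
#' @export
build_variant <- function(variant = c("seq2seq_weekly", "seq2seq", "bilstm", "lstm"),
                          spec, hidden_size = 64L,
                          context_rule = c("last", "mean"),
                          start_value = 0.5, seed = NULL) {
  variant <- match.arg(variant)
  context_rule <- match.arg(context_rule)
  if (!inherits(spec, "window_spec")) stop("spec must be a window_spec", call. = FALSE)
  spec$include_weekly_channel <- variant == "seq2seq_weekly"
  F_ <- n_features(spec)
  H <- as.integer(hidden_size)
  if (!is.null(seed)) set.seed(seed)
  m <- list(variant = variant, spec = spec, hidden_size = H,
            input_size = F_, context_rule = context_rule,
            start_value = start_value, trained = FALSE, history = NULL)
  if (variant %in% c("seq2seq_weekly", "seq2seq")) {
    m$enc <- lstm_params(F_, H)
    m$dec <- lstm_params(1L, H)
    m$out_W <- matrix(stats::runif(H, -1 / sqrt(H), 1 / sqrt(H)), H, 1)
    m$out_b <- 0
  } else if (variant == "bilstm") {
    m$enc <- lstm_params(F_, H)
    m$bwd <- lstm_params(F_, H)
    m$head_W <- matrix(stats::runif(2 * H * 24, -1 / sqrt(2 * H), 1 / sqrt(2 * H)),
                       2 * H, 24)
    m$head_b <- numeric(24)
  } else {
    m$enc <- lstm_params(F_, H)
    m$head_W <- matrix(stats::runif(H * 24, -1 / sqrt(H), 1 / sqrt(H)), H, 24)
    m$head_b <- numeric(24)
  }
  m$n_params <- sum(vapply(model_tensors(m), length, integer(1)))
  structure(m, class = "seq2seq_model")
}

#' @export
print.seq2seq_model <- function(x, ...) {
  cat(sprintf("seq2seq_model variant '%s': F = %d, hidden = %d, %d parameters%s\n",
              x$variant, x$input_size, x$hidden_size, x$n_params,
              if (x$trained) " (trained)" else ""))
  invisible(x)
}

lstm_tensor_fields <- c("Wi", "Wf", "Wo", "Wc", "Ui", "Uf", "Uo", "Uc",
                        "bi", "bf", "bo", "bc")

## flat named list of every trainable array in the model
model_tensors <- function(model) {
  out <- list()
  for (blk in c("enc", "dec", "bwd")) {
    if (is.null(model[[blk]])) next
    for (f in lstm_tensor_fields)
      out[[paste(blk, f, sep = ".")]] <- model[[blk]][[f]]
  }
  for (f in c("out_W", "out_b", "head_W", "head_b"))
    if (!is.null(model[[f]])) out[[f]] <- model[[f]]
  out
}

set_model_tensors <- function(model, tensors) {
  for (nm in names(tensors)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    if (length(parts) == 2L) model[[parts[1]]][[parts[2]]] <- tensors[[nm]]
    else model[[nm]] <- tensors[[nm]]
  }
  model
}

## encoder context under the model's context rule
encoder_context <- function(model, enc_out) {
  if (model$context_rule == "mean")
    list(h = Reduce(`+`, enc_out$hs) / length(enc_out$hs), c = enc_out$c)
  else
    list(h = enc_out$h, c = enc_out$c)
}

#' Encode an input window into a context
#'
#' Runs the encoder recurrence over the 24 input steps and returns the
#' context under the model's context rule (final state by default). The
#' context `h` and `c` each have the encoder hidden dimension.
#'
#' @param model A [build_variant()] model.
#' @param x A `24 x F` scaled input matrix (or a `sample_window`).
#' @return List with `h` and `c` vectors of length `hidden_size`.
#' @export
encode <- function(model, x) {
  if (inherits(x, "sample_window")) x <- x$x
  if (!is.matrix(x) || nrow(x) != 24L || ncol(x) != model$input_size)
    stop("shape error: expected a 24 x ", model$input_size, " input matrix",
         call. = FALSE)
  X <- lapply(seq_len(24), function(t) x[t, , drop = FALSE])
  out <- lstm_forward(model$enc, X)
  ctx <- encoder_context(model, out)
  list(h = drop(ctx$h), c = drop(ctx$c))
}

#' Decode a context into 24 scaled outputs
#'
#' Autoregressive generation: the decoder LSTM starts from the encoder
#' context, consumes its own previous output (the configured start value at
#' the first step), and projects each hidden state to one scaled
#' concentration. Applies to the `seq2seq_weekly` and `seq2seq` variants.
#'
#' @param model A [build_variant()] model (seq2seq variant).
#' @param context A context from [encode()].
#' @param y_seed First decoder input, in scaled space; defaults to the
#'   model's configured start value.
#' @return Numeric vector of 24 scaled outputs.
#' @export
decode <- function(model, context, y_seed = NULL) {
  if (!model$variant %in% c("seq2seq_weekly", "seq2seq"))
    stop("decode applies to the seq2seq variants", call. = FALSE)
  if (is.null(y_seed)) y_seed <- model$start_value
  st <- list(h = matrix(context$h, 1L), c = matrix(context$c, 1L))
  y_prev <- y_seed
  out <- numeric(24)
  for (t in 1:24) {
    st <- lstm_cell_step(model$dec, matrix(y_prev, 1L, 1L), st)
    out[t] <- drop(st$h %*% model$out_W) + model$out_b
    y_prev <- out[t]
  }
  out
}

## ---------------------------------------------------------------------------
## batched loss / gradients. X: list of 24 (B x F) matrices; Y: B x 24 scaled
## targets; tf_mask: logical(24), TRUE = feed observed y_{t-1} (training
## only). Fed-back outputs are treated as constants in the backward pass.
model_loss_grads <- function(model, X, Y, tf_mask = NULL, grads = TRUE) {
  B <- nrow(X[[1]])
  if (model$variant %in% c("seq2seq_weekly", "seq2seq")) {
    enc_out <- lstm_forward(model$enc, X)
    ctx <- encoder_context(model, enc_out)
    h <- ctx$h; c <- ctx$c
    dec_cache <- vector("list", 24L); dec_hs <- vector("list", 24L)
    yhat <- matrix(0, B, 24)
    x_t <- matrix(model$start_value, B, 1L)
    p <- model$dec
    for (t in 1:24) {
      i <- stats::plogis(addb(x_t %*% p$Wi + h %*% p$Ui, p$bi))
      f <- stats::plogis(addb(x_t %*% p$Wf + h %*% p$Uf, p$bf))
      o <- stats::plogis(addb(x_t %*% p$Wo + h %*% p$Uo, p$bo))
      g <- tanh(addb(x_t %*% p$Wc + h %*% p$Uc, p$bc))
      c_new <- f * c + i * g
      tc <- tanh(c_new)
      dec_cache[[t]] <- list(x = x_t, h_prev = h, c_prev = c,
                             i = i, f = f, o = o, g = g, tc = tc)
      h <- o * tc; c <- c_new
      dec_hs[[t]] <- h
      yhat[, t] <- drop(h %*% model$out_W) + model$out_b
      if (t < 24) {
        x_t <- if (!is.null(tf_mask) && tf_mask[t + 1L])
          Y[, t, drop = FALSE] else yhat[, t, drop = FALSE]
      }
    }
    loss <- mean((yhat - Y)^2)
    if (!grads) return(list(loss = loss, yhat = yhat))
    dY <- 2 * (yhat - Y) / (B * 24)
    g_outW <- matrix(0, model$hidden_size, 1)
    dhs_dec <- vector("list", 24L)
    for (t in 1:24) {
      g_outW <- g_outW + crossprod(dec_hs[[t]], dY[, t, drop = FALSE])
      dhs_dec[[t]] <- dY[, t, drop = FALSE] %*% t(model$out_W)
    }
    gdec <- lstm_backward(model$dec, dec_cache, dhs_dec)
    if (model$context_rule == "mean") {
      dhs_enc <- lapply(1:24, function(t) gdec$dh0 / 24)
      genc <- lstm_backward(model$enc, enc_out$cache, dhs_enc,
                            dc_last = gdec$dc0)
    } else {
      genc <- lstm_backward(model$enc, enc_out$cache,
                            dh_last = gdec$dh0, dc_last = gdec$dc0)
    }
    gr <- c(prefix_grads("enc", genc), prefix_grads("dec", gdec),
            list(out_W = g_outW, out_b = sum(dY)))
    list(loss = loss, yhat = yhat, grads = gr)
  } else if (model$variant == "bilstm") {
    fw <- lstm_forward(model$enc, X)
    bw <- lstm_forward(model$bwd, rev(X))
    hcat <- cbind(fw$h, bw$h)
    yhat <- addb(hcat %*% model$head_W, model$head_b)
    loss <- mean((yhat - Y)^2)
    if (!grads) return(list(loss = loss, yhat = yhat))
    dY <- 2 * (yhat - Y) / (B * 24)
    dh <- dY %*% t(model$head_W)
    H <- model$hidden_size
    gf <- lstm_backward(model$enc, fw$cache, dh_last = dh[, 1:H, drop = FALSE])
    gb <- lstm_backward(model$bwd, bw$cache,
                        dh_last = dh[, (H + 1):(2 * H), drop = FALSE])
    gr <- c(prefix_grads("enc", gf), prefix_grads("bwd", gb),
            list(head_W = crossprod(hcat, dY), head_b = colSums(dY)))
    list(loss = loss, yhat = yhat, grads = gr)
  } else {
    fw <- lstm_forward(model$enc, X)
    yhat <- addb(fw$h %*% model$head_W, model$head_b)
    loss <- mean((yhat - Y)^2)
    if (!grads) return(list(loss = loss, yhat = yhat))
    dY <- 2 * (yhat - Y) / (B * 24)
    genc <- lstm_backward(model$enc, fw$cache, dh_last = dY %*% t(model$head_W))
    gr <- c(prefix_grads("enc", genc),
            list(head_W = crossprod(fw$h, dY), head_b = colSums(dY)))
    list(loss = loss, yhat = yhat, grads = gr)
  }
}

prefix_grads <- function(prefix, g) {
  out <- g[lstm_tensor_fields]
  names(out) <- paste(prefix, lstm_tensor_fields, sep = ".")
  out
}

## Adam optimiser state over a flat tensor list
adam_init <- function(tensors) {
  list(m = lapply(tensors, function(x) 0 * x),
       v = lapply(tensors, function(x) 0 * x), t = 0L)
}

adam_step <- function(tensors, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(tensors)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    tensors[[nm]] <- tensors[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(tensors = tensors, state = state)
}

#' Train a forecasting model
#'
#' Minimises mean-squared error on scaled targets with Adam and
#' backpropagation through time. The seq2seq variants use teacher forcing at
#' the configured ratio during training only; inference is always fully
#' autoregressive. Early stopping monitors the validation loss when
#' `val_samples` are given (training loss otherwise) and restores the best
#' parameters.
#'
#' @param model A [build_variant()] model.
#' @param samples Training samples from [build_samples()] (>= 2).
#' @param cfg A [train_config()].
#' @param val_samples Optional validation samples for early stopping.
#' @return The trained model; `$history` is a data frame with per-epoch
#'   `train_loss` (and `val_loss`).
#' @export
train_model <- function(model, samples, cfg = train_config(), val_samples = NULL) {
  if (!inherits(cfg, "train_config")) stop("cfg must be a train_config", call. = FALSE)
  if (length(samples) < 2L) stop("need at least 2 training samples", call. = FALSE)
  set.seed(cfg$seed)
  tr <- stack_samples(samples)
  va <- if (length(val_samples)) stack_samples(val_samples)
  tensors <- model_tensors(model)
  opt <- adam_init(tensors)
  is_s2s <- model$variant %in% c("seq2seq_weekly", "seq2seq")
  best <- list(loss = Inf, tensors = tensors, epoch = 0L)
  hist_train <- numeric(0); hist_val <- numeric(0)
  wait <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    perm <- sample.int(tr$N)
    batch_starts <- seq(1L, tr$N, by = cfg$batch_size)
    ep_loss <- 0
    for (b0 in batch_starts) {
      idx <- perm[b0:min(b0 + cfg$batch_size - 1L, tr$N)]
      Xb <- lapply(tr$X, function(M) M[idx, , drop = FALSE])
      Yb <- tr$Y[idx, , drop = FALSE]
      tf_mask <- if (is_s2s && cfg$teacher_forcing_ratio > 0)
        stats::runif(24) < cfg$teacher_forcing_ratio
      model <- set_model_tensors(model, tensors)
      res <- model_loss_grads(model, Xb, Yb, tf_mask = tf_mask)
      if (!is.finite(res$loss)) stop("training error: loss diverged", call. = FALSE)
      upd <- adam_step(tensors, res$grads, opt, cfg$learning_rate)
      tensors <- upd$tensors; opt <- upd$state
      ep_loss <- ep_loss + res$loss * length(idx)
    }
    ep_loss <- ep_loss / tr$N
    hist_train <- c(hist_train, ep_loss)
    model <- set_model_tensors(model, tensors)
    monitor <- ep_loss
    if (!is.null(va)) {
      vres <- model_loss_grads(model, va$X, va$Y, grads = FALSE)
      hist_val <- c(hist_val, vres$loss)
      monitor <- vres$loss
    }
    if (monitor < best$loss - cfg$min_delta) {
      best <- list(loss = monitor, tensors = tensors, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }
  model <- set_model_tensors(model, best$tensors)
  model$trained <- TRUE
  model$history <- data.frame(
    epoch = seq_along(hist_train), train_loss = hist_train,
    val_loss = if (length(hist_val)) hist_val else NA_real_)
  model$best_epoch <- best$epoch
  model
}

#' Predict next-day concentrations in original units
#'
#' Runs the model on one or more samples (fully autoregressive for the
#' seq2seq variants) and inverse-scales the outputs to concentration units.
#'
#' @param model A trained model.
#' @param samples A single `sample_window` or a list of them.
#' @param scaler The fitted [fit_scaler()] used to build the samples.
#' @return A numeric vector of 24 concentrations for a single sample, or an
#'   `N x 24` matrix for a list.
#' @export
predict_model <- function(model, samples, scaler) {
  check_scaler(scaler)
  single <- inherits(samples, "sample_window")
  if (single) samples <- list(samples)
  st <- stack_samples(samples)
  res <- model_loss_grads(model, st$X, matrix(0, st$N, 24), grads = FALSE)
  out <- unscale_values(scaler, res$yhat,
                        channel = rep(model$spec$target_pollutant, 24))
  if (single) drop(out) else out
}
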