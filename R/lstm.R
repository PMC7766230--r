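## LSTM cell and batched forward/backward passes.
##
## The cell follows the standard gated recurrence with logistic gates and
## tanh activations:
##   i_t = sigma(W_i x_t + U_i h_{t-1} + b_i)
##   f_t = sigma(W_f x_t + U_f h_{t-1} + b_f)
##   o_t = sigma(W_o x_t + U_o h_{t-1} + b_o)
##   c~_t = tanh(W_c x_t + U_c h_{t-1} + b_c)
##   c_t = f_t * c_{t-1} + i_t * c~_t          (* = Hadamard)
##   h_t = o_t * tanh(c_t)
## Gradients are derived by hand and checked against finite differences in
## the test suite.

#' Initialise LSTM cell parameters
#'
#' Input-to-gate weights `W_*` are `input_size x hidden_size`, recurrent
#' weights `U_*` are `hidden_size x hidden_size`, biases length
#' `hidden_size`. Weights are drawn uniformly in `[-1/sqrt(H), 1/sqrt(H)]`
#' from the current RNG stream; the forget-gate bias starts at 1 (the usual
#' remember-by-default initialisation).
#'
#' @param input_size Number of input features.
#' @param hidden_size Hidden/cell state dimension.
#' @return An object of class `lstm_params`.
#' @export
lstm_params <- function(input_size, hidden_size) {
  k <- 1 / sqrt(hidden_size)
  rmat <- function(nr, nc) matrix(stats::runif(nr * nc, -k, k), nr, nc)
  p <- list(
    Wi = rmat(input_size, hidden_size), Wf = rmat(input_size, hidden_size),
    Wo = rmat(input_size, hidden_size), Wc = rmat(input_size, hidden_size),
    Ui = rmat(hidden_size, hidden_size), Uf = rmat(hidden_size, hidden_size),
    Uo = rmat(hidden_size, hidden_size), Uc = rmat(hidden_size, hidden_size),
    bi = numeric(hidden_size), bf = rep(1, hidden_size),
    bo = numeric(hidden_size), bc = numeric(hidden_size),
    input_size = input_size, hidden_size = hidden_size
  )
  class(p) <- "lstm_params"
  p
}

addb <- function(A, b) A + matrix(b, nrow(A), length(b), byrow = TRUE)

#' One LSTM cell step
#'
#' Advances the cell by one time step, exactly per the gated recurrence (see
#' the package vignette). Accepts a single input vector or a batch matrix
#' (rows = batch elements).
#'
#' @param params An [lstm_params()] object.
#' @param x_t Input: numeric vector of length `input_size`, or a batch
#'   matrix `B x input_size`.
#' @param state List with `h` and `c`, each a vector of length `hidden_size`
#'   or a `B x hidden_size` matrix; defaults to zeros.
#' @return List with the new `h` and `c` (same shape as the input state).
#' @export
lstm_cell_step <- function(params, x_t, state = NULL) {
  vec_in <- !is.matrix(x_t)
  if (vec_in) x_t <- matrix(x_t, 1L)
  if (ncol(x_t) != params$input_size)
    stop("shape error: x_t has ", ncol(x_t), " features, expected ",
         params$input_size, call. = FALSE)
  B <- nrow(x_t); H <- params$hidden_size
  if (is.null(state)) state <- list(h = matrix(0, B, H), c = matrix(0, B, H))
  h <- state$h; c <- state$c
  if (!is.matrix(h)) {
    if (length(h) != H) stop("shape error: state h has length ", length(h),
                             ", expected ", H, call. = FALSE)
    h <- matrix(h, B, H, byrow = TRUE)
  }
  if (!is.matrix(c)) {
    if (length(c) != H) stop("shape error: state c has length ", length(c),
                             ", expected ", H, call. = FALSE)
    c <- matrix(c, B, H, byrow = TRUE)
  }
  if (ncol(h) != H || ncol(c) != H)
    stop("shape error: state dimension does not match hidden_size", call. = FALSE)
  i <- stats::plogis(addb(x_t %*% params$Wi + h %*% params$Ui, params$bi))
  f <- stats::plogis(addb(x_t %*% params$Wf + h %*% params$Uf, params$bf))
  o <- stats::plogis(addb(x_t %*% params$Wo + h %*% params$Uo, params$bo))
  g <- tanh(addb(x_t %*% params$Wc + h %*% params$Uc, params$bc))
  c_new <- f * c + i * g
  h_new <- o * tanh(c_new)
  if (vec_in) list(h = drop(h_new), c = drop(c_new))
  else list(h = h_new, c = c_new)
}

## batched forward over a list of T input matrices (each B x F), caching the
## intermediates the backward pass needs
lstm_forward <- function(p, X, h0 = NULL, c0 = NULL) {
  T_ <- length(X); B <- nrow(X[[1]]); H <- p$hidden_size
  h <- if (is.null(h0)) matrix(0, B, H) else h0
  c <- if (is.null(c0)) matrix(0, B, H) else c0
  hs <- vector("list", T_); cache <- vector("list", T_)
  for (t in seq_len(T_)) {
    x <- X[[t]]
    i <- stats::plogis(addb(x %*% p$Wi + h %*% p$Ui, p$bi))
    f <- stats::plogis(addb(x %*% p$Wf + h %*% p$Uf, p$bf))
    o <- stats::plogis(addb(x %*% p$Wo + h %*% p$Uo, p$bo))
    g <- tanh(addb(x %*% p$Wc + h %*% p$Uc, p$bc))
    c_new <- f * c + i * g
    tc <- tanh(c_new)
    h_new <- o * tc
    cache[[t]] <- list(x = x, h_prev = h, c_prev = c,
                       i = i, f = f, o = o, g = g, tc = tc)
    h <- h_new; c <- c_new
    hs[[t]] <- h
  }
  list(h = h, c = c, hs = hs, cache = cache)
}

zero_like_lstm <- function(p) {
  list(Wi = 0 * p$Wi, Wf = 0 * p$Wf, Wo = 0 * p$Wo, Wc = 0 * p$Wc,
       Ui = 0 * p$Ui, Uf = 0 * p$Uf, Uo = 0 * p$Uo, Uc = 0 * p$Uc,
       bi = 0 * p$bi, bf = 0 * p$bf, bo = 0 * p$bo, bc = 0 * p$bc)
}

## backward through time. dhs: optional per-step gradients on h_t (list or
## NULL entries); dh_last/dc_last: gradients flowing into the final state.
## Returns parameter gradients plus dh0/dc0 (gradient on the initial state).
lstm_backward <- function(p, cache, dhs = NULL, dh_last = NULL, dc_last = NULL) {
  T_ <- length(cache)
  B <- nrow(cache[[1]]$x); H <- p$hidden_size
  g <- zero_like_lstm(p)
  dh <- if (is.null(dh_last)) matrix(0, B, H) else dh_last
  dc <- if (is.null(dc_last)) matrix(0, B, H) else dc_last
  for (t in rev(seq_len(T_))) {
    ca <- cache[[t]]
    if (!is.null(dhs) && !is.null(dhs[[t]])) dh <- dh + dhs[[t]]
    do_ <- dh * ca$tc
    dc <- dc + dh * ca$o * (1 - ca$tc^2)
    di <- dc * ca$g
    dg <- dc * ca$i
    df <- dc * ca$c_prev
    dc <- dc * ca$f
    dai <- di * ca$i * (1 - ca$i)
    daf <- df * ca$f * (1 - ca$f)
    dao <- do_ * ca$o * (1 - ca$o)
    dag <- dg * (1 - ca$g^2)
    g$Wi <- g$Wi + crossprod(ca$x, dai)
    g$Wf <- g$Wf + crossprod(ca$x, daf)
    g$Wo <- g$Wo + crossprod(ca$x, dao)
    g$Wc <- g$Wc + crossprod(ca$x, dag)
    g$Ui <- g$Ui + crossprod(ca$h_prev, dai)
    g$Uf <- g$Uf + crossprod(ca$h_prev, daf)
    g$Uo <- g$Uo + crossprod(ca$h_prev, dao)
    g$Uc <- g$Uc + crossprod(ca$h_prev, dag)
    g$bi <- g$bi + colSums(dai)
    g$bf <- g$bf + colSums(daf)
    g$bo <- g$bo + colSums(dao)
    g$bc <- g$bc + colSums(dag)
    dh <- dai %*% t(p$Ui) + daf %*% t(p$Uf) +
      dao %*% t(p$Uo) + dag %*% t(p$Uc)
  }
  g$dh0 <- dh
  g$dc0 <- dc
  g
}
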