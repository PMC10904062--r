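# Batched recurrent cell forward/backward passes.  All activations are
# explicit so the backward passes can be written (and finite-difference
# checked) by hand; no external autodiff runtime is involved.
#
# Gate layout follows the two-bias convention: for a GRU the stacked gate
# pre-activations are [r; z; n], for an LSTM [i; f; g; o].  Inputs are
# B x in matrices (rows = batch members).

gru_forward <- function(inp, h_prev, lp) {
  h <- length(lp$b_ih) / 3L
  gi <- add_rowvec(inp %*% t(lp$W_ih), lp$b_ih)
  gh <- add_rowvec(h_prev %*% t(lp$W_hh), lp$b_hh)
  ir <- seq_len(h); iz <- h + ir; inn <- 2L * h + ir
  r <- sigmoid(gi[, ir, drop = FALSE] + gh[, ir, drop = FALSE])
  z <- sigmoid(gi[, iz, drop = FALSE] + gh[, iz, drop = FALSE])
  ghn <- gh[, inn, drop = FALSE]
  n <- tanh(gi[, inn, drop = FALSE] + r * ghn)
  h_new <- (1 - z) * n + z * h_prev
  list(h = h_new,
       cache = list(inp = inp, h_prev = h_prev, r = r, z = z, n = n,
                    ghn = ghn))
}

gru_backward <- function(dh, cache, lp, acc) {
  r <- cache$r; z <- cache$z; n <- cache$n
  dz <- dh * (cache$h_prev - n) * z * (1 - z)
  dn <- dh * (1 - z) * (1 - n * n)
  dghn <- dn * r
  dr <- dn * cache$ghn * r * (1 - r)
  dgi <- cbind(dr, dz, dn)
  dgh <- cbind(dr, dz, dghn)
  acc$W_ih <- acc$W_ih + crossprod(dgi, cache$inp)
  acc$b_ih <- acc$b_ih + colSums(dgi)
  acc$W_hh <- acc$W_hh + crossprod(dgh, cache$h_prev)
  acc$b_hh <- acc$b_hh + colSums(dgh)
  list(d_inp = dgi %*% lp$W_ih,
       dh_prev = dgh %*% lp$W_hh + dh * z,
       acc = acc)
}

lstm_forward <- function(inp, h_prev, c_prev, lp) {
  h <- length(lp$b_ih) / 4L
  a <- add_rowvec(inp %*% t(lp$W_ih), lp$b_ih) +
    add_rowvec(h_prev %*% t(lp$W_hh), lp$b_hh)
  ii <- seq_len(h)
  i <- sigmoid(a[, ii, drop = FALSE])
  f <- sigmoid(a[, h + ii, drop = FALSE])
  g <- tanh(a[, 2L * h + ii, drop = FALSE])
  o <- sigmoid(a[, 3L * h + ii, drop = FALSE])
  c_new <- f * c_prev + i * g
  tc <- tanh(c_new)
  h_new <- o * tc
  list(h = h_new, c = c_new,
       cache = list(inp = inp, h_prev = h_prev, c_prev = c_prev,
                    i = i, f = f, g = g, o = o, tc = tc))
}

lstm_backward <- function(dh, dc_next, cache, lp, acc) {
  i <- cache$i; f <- cache$f; g <- cache$g; o <- cache$o; tc <- cache$tc
  do_ <- dh * tc * o * (1 - o)
  dc <- dc_next + dh * o * (1 - tc * tc)
  di <- dc * g * i * (1 - i)
  df <- dc * cache$c_prev * f * (1 - f)
  dg <- dc * i * (1 - g * g)
  da <- cbind(di, df, dg, do_)
  acc$W_ih <- acc$W_ih + crossprod(da, cache$inp)
  acc$b_ih <- acc$b_ih + colSums(da)
  acc$W_hh <- acc$W_hh + crossprod(da, cache$h_prev)
  acc$b_hh <- acc$b_hh + colSums(da)
  list(d_inp = da %*% lp$W_ih,
       dh_prev = da %*% lp$W_hh,
       dc_prev = dc * f,
       acc = acc)
}

fb_net_forward <- function(u, params, config) {
  a <- list()
  cur <- u
  for (d in seq_len(config$feedback_depth)) {
    cur <- tanh(add_rowvec(cur %*% t(params$fb$W[[d]]), params$fb$b[[d]]))
    a[[d]] <- cur
  }
  list(f = cur, cache = list(u = u, a = a))
}

fb_net_backward <- function(df, cache, params, config, acc) {
  for (d in rev(seq_len(config$feedback_depth))) {
    ad <- cache$a[[d]]
    dpre <- df * (1 - ad * ad)
    prev <- if (d == 1L) cache$u else cache$a[[d - 1L]]
    acc$W[[d]] <- acc$W[[d]] + crossprod(dpre, prev)
    acc$b[[d]] <- acc$b[[d]] + colSums(dpre)
    df <- dpre %*% params$fb$W[[d]]
  }
  list(du = df, acc = acc)
}

#' The feedback network
#'
#' Concatenates the lagged prediction/label pair (and, for regularized
#' variants, the predicted/actual current input vectors) and passes them
#' through the feedback feedforward layers (tanh).  The resulting vector
#' is shared across all recurrent layers of the step.  During training,
#' backpropagation is severed where `y_hat_lag` / `x_hat_cur` enter this
#' network when `stop_gradient` is on; the trained default constants used
#' for `t <= lag` are leaf parameters and always receive their gradient.
#'
#' @param fb List with `y_hat_lag`, `y_true_lag`, optionally `x_hat_cur`
#'   and `x_cur` (regularized variants only), and `is_default` (when
#'   `TRUE` the trained default constants in `params$defaults` are used
#'   instead of the supplied lagged values).
#' @param params An `aki_params` with a feedback block.
#' @param config The matching `aki_model_config`.
#' @return Numeric feedback vector of length `config$feedback_hidden`.
#' @export
feedback_network <- function(fb, params, config) {
  stopifnot(inherits(config, "aki_model_config"), config$has_feedback)
  if (isTRUE(fb$is_default)) {
    fb$y_hat_lag <- params$defaults$y_hat
    fb$y_true_lag <- params$defaults$y
  }
  u <- c(fb$y_hat_lag, fb$y_true_lag)
  if (config$regularized) {
    if (is.null(fb$x_hat_cur) || is.null(fb$x_cur))
      stopf("regularized variants need 'x_hat_cur' and 'x_cur' feedback")
    u <- c(u, fb$x_hat_cur, fb$x_cur)
  } else if (!is.null(fb$x_hat_cur))
    stopf("variant '%s' takes no input-prediction feedback", config$variant)
  if (length(u) != fb_input_dim(config))
    stopf("feedback input has length %d, expected %d",
          length(u), fb_input_dim(config))
  drop(fb_net_forward(matrix(u, 1L), params, config)$f)
}

#' One self-correcting recurrent step
#'
#' Runs the feedback network, feeds `[layer input, feedback vector]` into
#' each recurrent layer, and applies the output head(s) to the top hidden
#' state.  Evaluation-mode (no dropout); the batched training engine
#' shares the same cell functions.
#'
#' @param x_t Input feature vector (length `config$input_dim`).
#' @param state List with `h` (list of per-layer hidden vectors) and, for
#'   LSTM, `c`.  Use [init_state()] for the zero initial state.
#' @param fb Feedback inputs as in [feedback_network()].
#' @param params,config Model parameters and config.
#' @return List with `y_hat` (probability, or predicted scaled urine for
#'   the regression variant), `x_hat_next` (regularized variants), and
#'   the updated `state`.
#' @export
sc_step <- function(x_t, state, fb, params, config) {
  stopifnot(config$has_feedback)
  f <- feedback_network(fb, params, config)
  inp <- matrix(x_t, 1L)
  new_h <- state$h; new_c <- state$c
  for (l in seq_len(config$n_layers)) {
    i_l <- cbind(inp, matrix(f, 1L))
    if (config$cell_type == "gru") {
      st <- gru_forward(i_l, matrix(state$h[[l]], 1L), params$layers[[l]])
      new_h[[l]] <- drop(st$h)
    } else {
      st <- lstm_forward(i_l, matrix(state$h[[l]], 1L),
                         matrix(state$c[[l]], 1L), params$layers[[l]])
      new_h[[l]] <- drop(st$h)
      new_c[[l]] <- drop(st$c)
    }
    inp <- st$h
  }
  if (!all(is.finite(inp))) stopf("non-finite activations in sc_step")
  logit <- drop(inp %*% params$head$w) + params$head$b
  y_hat <- if (config$regression) logit else sigmoid(logit)
  out <- list(y_hat = y_hat, state = list(h = new_h, c = new_c))
  if (config$regularized)
    out$x_hat_next <- drop(inp %*% t(params$xhead$W)) + params$xhead$b
  out
}

#' Zero initial recurrent state
#' @param config An `aki_model_config`.
#' @return List with per-layer zero `h` (and `c` for LSTM).
#' @export
init_state <- function(config) {
  z <- lapply(seq_len(config$n_layers),
              function(l) numeric(config$hidden_size))
  list(h = z, c = if (config$cell_type == "lstm") z else NULL)
}
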