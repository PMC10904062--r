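# Batched forward/backward engines.
#
# Stays are padded to the longest length in the batch; every loss term
# carries an explicit per-(stay, hour) coefficient, so padded positions
# and undefined labels contribute exactly zero to both the loss and the
# gradients (their adjoints vanish identically along the backward
# recursion).  The self-correcting engine runs time-major because the
# feedback at step t needs y_hat from step t-L and x_hat from step t-1;
# the baseline engine runs layer-major, which is what makes inter-layer
# self-attention straightforward.

zero_like <- function(x) {
  if (is.list(x)) return(lapply(x, zero_like))
  if (is.matrix(x)) matrix(0, nrow(x), ncol(x)) else numeric(length(x))
}

# Per-element loss coefficients; class weight folded in so that the loss
# is  sum(M * ce_elem)  and  d/dlogit = M * (p - y).
make_loss_spec <- function(config, y, Tlens, class_weight = 1) {
  B <- nrow(y); T_max <- ncol(y)
  def <- is.finite(y)
  for (b in seq_len(B)) if (Tlens[b] < T_max) def[b, (Tlens[b] + 1L):T_max] <- FALSE
  n_def <- rowSums(def)
  if (any(n_def == 0L)) stopf("a stay has no defined labels")
  base <- def / (n_def * B)
  M <- if (config$regression) base else base * ifelse(def & y == 1, class_weight, 1)
  ylab <- ifelse(def, y, 0)
  Creg <- NULL
  if (config$regularized && config$lambda > 0) {
    Creg <- matrix(0, B, T_max + 1L)
    for (b in seq_len(B)) if (Tlens[b] >= 2L)
      Creg[b, 2:Tlens[b]] <- config$lambda /
        (config$input_dim * (Tlens[b] - 1L) * B)
  }
  list(M = M, ylab = ylab, Creg = Creg, def = def)
}

# X: B x D x T array (zero padded); fby: B x T teacher series for the
# feedback (zero padded; checked for availability at used lags).
sc_batch <- function(params, config, X, fby, Tlens,
                     loss_spec = NULL, grad = FALSE, train = FALSE,
                     inject = NULL) {
  stopifnot(config$has_feedback)
  B <- dim(X)[1]; D <- dim(X)[2]; T_max <- dim(X)[3]
  h <- config$hidden_size; NL <- config$n_layers; L <- config$lag
  lstm <- config$cell_type == "lstm"
  reg <- config$regularized
  sg <- config$stop_gradient
  keep <- 1 - config$dropout_rate
  use_drop <- train && config$dropout_rate > 0

  for (b in seq_len(B)) {
    tt <- seq_len(Tlens[b])
    used <- tt[tt > L]
    if (length(used) && any(!is.finite(fby[b, used - L])))
      stopf("missing lagged feedback label for stay %d at t > lag", b)
  }
  fby[!is.finite(fby)] <- 0

  slab <- function(A, t) matrix(A[, , t], B, D)
  hs <- lapply(seq_len(NL), function(l) matrix(0, B, h))
  cs <- if (lstm) hs
  yhat <- logits <- matrix(0, B, T_max)
  xhat <- if (reg) array(0, c(B, D, T_max + 1L))
  if (reg) xhat[, , 1L] <- matrix(params$defaults$x_hat, B, D, byrow = TRUE)
  caches <- vector("list", T_max)

  for (t in seq_len(T_max)) {
    if (t <= L) {
      u12 <- cbind(rep(params$defaults$y_hat, B), rep(params$defaults$y, B))
    } else {
      ylag <- yhat[, t - L]
      if (!is.null(inject) && inject$step == t) ylag <- ylag + inject$eps
      u12 <- cbind(ylag, fby[, t - L])
    }
    u <- if (reg) cbind(u12, slab(xhat, t), slab(X, t)) else u12
    fbf <- fb_net_forward(u, params, config)
    inp <- slab(X, t)
    layer_caches <- vector("list", NL)
    dmasks <- if (use_drop) vector("list", NL)
    for (l in seq_len(NL)) {
      i_l <- cbind(inp, fbf$f)
      if (lstm) {
        st <- lstm_forward(i_l, hs[[l]], cs[[l]], params$layers[[l]])
        cs[[l]] <- st$c
      } else {
        st <- gru_forward(i_l, hs[[l]], params$layers[[l]])
      }
      hs[[l]] <- st$h
      layer_caches[[l]] <- st$cache
      out_l <- st$h
      if (use_drop) {
        dm <- matrix(stats::runif(B * h) < keep, B, h) / keep
        dmasks[[l]] <- dm
        out_l <- out_l * dm
      }
      inp <- out_l
    }
    top <- inp
    lg <- drop(top %*% params$head$w) + params$head$b
    logits[, t] <- lg
    yhat[, t] <- if (config$regression) lg else sigmoid(lg)
    if (reg) {
      xhat[, , t + 1L] <- add_rowvec(top %*% t(params$xhead$W),
                                     params$xhead$b)
    }
    caches[[t]] <- list(fb = fbf$cache, layers = layer_caches,
                        dmasks = dmasks, top = top)
  }
  if (any(!is.finite(logits)))
    stopf("non-finite activations in forward pass")

  out <- list(y_hat = yhat, x_hat = xhat, logits = logits)

  if (!is.null(loss_spec)) {
    M <- loss_spec$M; ylab <- loss_spec$ylab
    p <- pmin(pmax(yhat, 1e-12), 1 - 1e-12)
    label_loss <- if (config$regression)
      sum(M * (yhat - ylab)^2)
    else
      -sum(M * (ylab * log(p) + (1 - ylab) * log1p(-p)))
    reg_loss <- 0
    if (!is.null(loss_spec$Creg)) {
      for (t in 2:T_max) {
        dd <- slab(xhat, t) - slab(X, t)
        reg_loss <- reg_loss + sum(loss_spec$Creg[, t] * rowSums(dd * dd))
      }
    }
    out$label_loss <- label_loss
    out$reg_loss <- reg_loss
    out$loss <- label_loss + reg_loss
  }

  if (!grad) return(out)
  stopifnot(!is.null(loss_spec))
  M <- loss_spec$M; ylab <- loss_spec$ylab; Creg <- loss_spec$Creg

  acc <- zero_like(unclass(params))
  pending_dyhat <- matrix(0, B, T_max)
  pending_dxhat <- if (reg) array(0, c(B, D, T_max + 1L))
  dh_next <- lapply(seq_len(NL), function(l) matrix(0, B, h))
  dc_next <- if (lstm) dh_next
  fbD <- config$feedback_hidden

  for (t in rev(seq_len(T_max))) {
    cc <- caches[[t]]
    dlogit <- if (config$regression)
      2 * M[, t] * (yhat[, t] - ylab[, t])
    else
      M[, t] * (yhat[, t] - ylab[, t])
    if (!sg) {
      pd <- pending_dyhat[, t]
      dlogit <- dlogit + if (config$regression) pd
        else pd * yhat[, t] * (1 - yhat[, t])
    }
    acc$head$w <- acc$head$w + drop(crossprod(cc$top, dlogit))
    acc$head$b <- acc$head$b + sum(dlogit)
    dtop <- outer(dlogit, params$head$w)
    if (reg) {
      dxh <- if (!is.null(Creg))
        2 * Creg[, t + 1L] * (slab(xhat, t + 1L) - X2_col(X, t + 1L, B, D))
      else matrix(0, B, D)
      if (!sg) dxh <- dxh + slab(pending_dxhat, t + 1L)
      if (any(dxh != 0)) {
        acc$xhead$W <- acc$xhead$W + crossprod(dxh, cc$top)
        acc$xhead$b <- acc$xhead$b + colSums(dxh)
        dtop <- dtop + dxh %*% params$xhead$W
      }
    }
    dh_above <- if (use_drop) dtop * cc$dmasks[[NL]] else dtop
    df <- matrix(0, B, fbD)
    for (l in rev(seq_len(NL))) {
      dh_l <- dh_above + dh_next[[l]]
      if (lstm) {
        res <- lstm_backward(dh_l, dc_next[[l]], cc$layers[[l]],
                             params$layers[[l]], acc$layers[[l]])
        dc_next[[l]] <- res$dc_prev
      } else {
        res <- gru_backward(dh_l, cc$layers[[l]],
                            params$layers[[l]], acc$layers[[l]])
      }
      acc$layers[[l]] <- res$acc
      dh_next[[l]] <- res$dh_prev
      inD <- ncol(cc$layers[[l]]$inp) - fbD
      df <- df + res$d_inp[, inD + seq_len(fbD), drop = FALSE]
      if (l > 1L) {
        d_out <- res$d_inp[, seq_len(inD), drop = FALSE]
        dh_above <- if (use_drop) d_out * cc$dmasks[[l - 1L]] else d_out
      }
    }
    fbres <- fb_net_backward(df, cc$fb, params, config, acc$fb)
    acc$fb <- fbres$acc
    du <- fbres$du
    if (t <= L) {
      acc$defaults$y_hat <- acc$defaults$y_hat + sum(du[, 1L])
      acc$defaults$y <- acc$defaults$y + sum(du[, 2L])
    } else if (!sg) {
      pending_dyhat[, t - L] <- pending_dyhat[, t - L] + du[, 1L]
    }
    if (reg) {
      du_xh <- du[, 2L + seq_len(D), drop = FALSE]
      if (t == 1L) {
        acc$defaults$x_hat <- acc$defaults$x_hat + colSums(du_xh)
      } else if (!sg) {
        pending_dxhat[, , t] <- slab(pending_dxhat, t) + du_xh
      }
    }
  }
  out$grads <- acc
  out$dyhat_feedback <- pending_dyhat
  out
}

# array slice helper tolerating the out-of-range column t = T_max + 1
X2_col <- function(X, t, B, D) {
  if (t > dim(X)[3]) matrix(0, B, D) else matrix(X[, , t], B, D)
}

att_forward <- function(H_list, ap, causal) {
  B <- nrow(H_list[[1]]); h <- ncol(H_list[[1]]); T_max <- length(H_list)
  Harr <- array(unlist(H_list, use.names = FALSE), c(B, h, T_max))
  O <- array(0, c(B, h, T_max))
  cache <- vector("list", B)
  scale <- 1 / sqrt(h)
  for (b in seq_len(B)) {
    Hb <- t(matrix(Harr[b, , ], h, T_max))
    Q <- Hb %*% ap$Wq; K <- Hb %*% ap$Wk; V <- Hb %*% ap$Wv
    S <- tcrossprod(Q, K) * scale
    if (causal) S[upper.tri(S)] <- -Inf
    S <- S - apply(S, 1, max)
    E <- exp(S)
    A <- E / rowSums(E)
    Ob <- A %*% V
    O[b, , ] <- t(Ob)
    cache[[b]] <- list(Hb = Hb, Q = Q, K = K, V = V, A = A)
  }
  list(O_list = lapply(seq_len(T_max), function(t) matrix(O[, , t], B, h)),
       cache = cache, scale = scale)
}

att_backward <- function(dO_list, att_cache, ap, acc) {
  B <- nrow(dO_list[[1]]); T_max <- length(dO_list)
  h <- ncol(dO_list[[1]])
  dOarr <- array(unlist(dO_list, use.names = FALSE), c(B, h, T_max))
  dH <- array(0, c(B, h, T_max))
  for (b in seq_len(B)) {
    cb <- att_cache$cache[[b]]
    dOb <- t(matrix(dOarr[b, , ], h, T_max))
    A <- cb$A
    dA <- tcrossprod(dOb, cb$V)
    dV <- crossprod(A, dOb)
    dS <- (dA - rowSums(dA * A)) * A
    dQ <- dS %*% cb$K * att_cache$scale
    dK <- crossprod(dS, cb$Q) * att_cache$scale
    acc$Wq <- acc$Wq + crossprod(cb$Hb, dQ)
    acc$Wk <- acc$Wk + crossprod(cb$Hb, dK)
    acc$Wv <- acc$Wv + crossprod(cb$Hb, dV)
    dHb <- dQ %*% t(ap$Wq) + dK %*% t(ap$Wk) + dV %*% t(ap$Wv)
    dH[b, , ] <- t(dHb)
  }
  list(dH_list = lapply(seq_len(T_max),
                        function(t) matrix(dH[, , t], B, h)),
       acc = acc)
}

baseline_batch <- function(params, config, X, Tlens,
                           loss_spec = NULL, grad = FALSE, train = FALSE) {
  stopifnot(!config$has_feedback)
  B <- dim(X)[1]; T_max <- dim(X)[3]
  h <- config$hidden_size; NL <- config$n_layers
  lstm <- config$cell_type == "lstm"
  keep <- 1 - config$dropout_rate
  use_drop <- train && config$dropout_rate > 0

  D_in <- dim(X)[2]
  inp_list <- lapply(seq_len(T_max), function(t) matrix(X[, , t], B, D_in))
  layer_data <- vector("list", NL)
  for (l in seq_len(NL)) {
    hp <- matrix(0, B, h); cp <- if (lstm) matrix(0, B, h)
    cellc <- vector("list", T_max)
    H <- vector("list", T_max)
    for (t in seq_len(T_max)) {
      if (lstm) {
        st <- lstm_forward(inp_list[[t]], hp, cp, params$layers[[l]])
        cp <- st$c
      } else {
        st <- gru_forward(inp_list[[t]], hp, params$layers[[l]])
      }
      hp <- st$h
      cellc[[t]] <- st$cache
      H[[t]] <- st$h
    }
    att_cache <- NULL
    out_list <- H
    if (config$attention) {
      att_cache <- att_forward(H, params$attn[[l]], config$attention_causal)
      out_list <- att_cache$O_list
    }
    dmasks <- NULL
    if (use_drop) {
      dmasks <- lapply(seq_len(T_max), function(t)
        matrix(stats::runif(B * h) < keep, B, h) / keep)
      out_list <- lapply(seq_len(T_max),
                         function(t) out_list[[t]] * dmasks[[t]])
    }
    layer_data[[l]] <- list(cellc = cellc, att = att_cache,
                            dmasks = dmasks, inp = inp_list)
    inp_list <- out_list
  }
  top_list <- inp_list
  logits <- vapply(seq_len(T_max), function(t)
    drop(top_list[[t]] %*% params$head$w) + params$head$b, numeric(B))
  logits <- matrix(logits, B, T_max)
  yhat <- sigmoid(logits)

  out <- list(y_hat = yhat, logits = logits)
  if (!is.null(loss_spec)) {
    M <- loss_spec$M; ylab <- loss_spec$ylab
    p <- pmin(pmax(yhat, 1e-12), 1 - 1e-12)
    out$label_loss <- -sum(M * (ylab * log(p) + (1 - ylab) * log1p(-p)))
    out$reg_loss <- 0
    out$loss <- out$label_loss
  }
  if (!grad) return(out)

  M <- loss_spec$M; ylab <- loss_spec$ylab
  acc <- zero_like(unclass(params))
  dout_list <- vector("list", T_max)
  for (t in seq_len(T_max)) {
    dlogit <- M[, t] * (yhat[, t] - ylab[, t])
    acc$head$w <- acc$head$w + drop(crossprod(top_list[[t]], dlogit))
    acc$head$b <- acc$head$b + sum(dlogit)
    dout_list[[t]] <- outer(dlogit, params$head$w)
  }
  for (l in rev(seq_len(NL))) {
    ld <- layer_data[[l]]
    if (use_drop)
      dout_list <- lapply(seq_len(T_max),
                          function(t) dout_list[[t]] * ld$dmasks[[t]])
    if (config$attention) {
      ares <- att_backward(dout_list, ld$att, params$attn[[l]],
                           acc$attn[[l]])
      acc$attn[[l]] <- ares$acc
      dout_list <- ares$dH_list
    }
    dh_prev <- matrix(0, B, h); dc_prev <- if (lstm) matrix(0, B, h)
    d_inp_list <- vector("list", T_max)
    for (t in rev(seq_len(T_max))) {
      dh_t <- dout_list[[t]] + dh_prev
      if (lstm) {
        res <- lstm_backward(dh_t, dc_prev, ld$cellc[[t]],
                             params$layers[[l]], acc$layers[[l]])
        dc_prev <- res$dc_prev
      } else {
        res <- gru_backward(dh_t, ld$cellc[[t]],
                            params$layers[[l]], acc$layers[[l]])
      }
      acc$layers[[l]] <- res$acc
      dh_prev <- res$dh_prev
      d_inp_list[[t]] <- res$d_inp
    }
    dout_list <- d_inp_list
  }
  out$grads <- acc
  out
}

#' Forward pass over one stay (self-correcting variants)
#'
#' Reference single-stay interface (evaluation mode, no dropout).  For
#' `t <= lag` the trained default feedback constants are used; for
#' regularized variants the input prediction made at `t-1` is fed back at
#' `t` (with a trained default at `t = 1`).  The teacher labels at
#' `t - lag` are the true labels — legitimately available at inference
#' time because AKI labels are observed `lag` hours after the fact.
#'
#' @param features T x D' feature matrix.
#' @param fb_labels Teacher series for the feedback; entry `t - lag` must
#'   be finite for every `t > lag` (for classification, the label series
#'   `y`; for the regression variant, the scaled urine target).
#' @param config,params Model configuration and parameters.
#' @return List with `y_hat` (length-T predictions) and `x_hat`
#'   ((T+1) x D' input predictions, row t = prediction for hour t;
#'   regularized variants only).
#' @export
forward_stay <- function(features, fb_labels, config, params) {
  T_hours <- nrow(features)
  X <- aperm(array(features, c(T_hours, ncol(features), 1L)), c(3L, 2L, 1L))
  fby <- matrix(fb_labels, 1L, T_hours)
  res <- sc_batch(params, config, X, fby, Tlens = T_hours)
  out <- list(y_hat = drop(res$y_hat))
  if (config$regularized)
    out$x_hat <- t(matrix(res$x_hat, ncol(features), T_hours + 1L))
  out
}

#' Forward pass over one stay (baseline variants)
#'
#' Stacked GRU/LSTM, optionally with causal self-attention over each
#' layer's per-step outputs (evaluation mode).
#'
#' @param features T x D' feature matrix.
#' @param config,params Model configuration (variant `baseline` or
#'   `baseline_attention`) and parameters.
#' @return Length-T vector of predicted probabilities.
#' @export
baseline_forward <- function(features, config, params) {
  T_hours <- nrow(features)
  X <- aperm(array(features, c(T_hours, ncol(features), 1L)), c(3L, 2L, 1L))
  drop(baseline_batch(params, config, X, Tlens = T_hours)$y_hat)
}
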