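# Shared fixtures, all built in code.

# A hand-made raw stay: every registry variable present, hourly where the
# class is hourly, with a configurable override for one variable's events.
manual_stay <- function(T_hours = 6L, weight = 80,
                        override_var = NULL, override_events = NULL,
                        stay_id = "stay_manual") {
  vars <- aki_variables()
  ev <- do.call(rbind, lapply(vars$name, function(v) {
    if (!is.null(override_var) && v == override_var) return(NULL)
    data.frame(time = seq_len(T_hours) - 0.5, variable = v,
               value = rep(1, T_hours))
  }))
  if (!is.null(override_events))
    ev <- rbind(ev, data.frame(time = override_events$time,
                               variable = override_var,
                               value = override_events$value))
  structure(list(
    stay_id = stay_id,
    static = list(age = 60, gender = 1, weight = weight,
                  comorbidities = rep(0L, 25)),
    events = ev[order(ev$time, ev$variable), ],
    length_hours = as.integer(T_hours)
  ), class = "aki_raw_stay")
}

small_cohort <- function(n = 20L, seed = 7L, ...) {
  build_cohort(simulate_cohort(sim_config(n_stays = n, seed = seed, ...)))
}

# Brute-force labeling oracles (independent double loops).
brute_next6 <- function(rate, horizon = 6L) {
  T_hours <- length(rate)
  y <- rep(NA_real_, T_hours)
  for (t in seq_len(T_hours)) {
    if (t + horizon > T_hours) next
    ok <- TRUE
    for (s in (t + 1):(t + horizon)) if (!(rate[s] < 0.5)) ok <- FALSE
    y[t] <- as.numeric(ok)
  }
  y
}

brute_onset <- function(rate, window = 6L) {
  T_hours <- length(rate)
  onset <- integer(T_hours)
  for (t in seq_len(T_hours)) {
    if (t < window) next
    ok <- TRUE
    for (s in (t - window + 1):t) if (!(rate[s] < 0.5)) ok <- FALSE
    onset[t] <- as.integer(ok)
  }
  onset
}

# Embed baseline GRU parameters into a self-correcting parameter set with
# the feedback path exactly silenced: output layer of the feedback net
# zeroed (so the feedback vector is identically 0) and the feedback input
# columns of every recurrent layer zeroed.
silenced_sc_params <- function(base_params, sc_config, sc_params) {
  p <- sc_params
  fbD <- sc_config$feedback_hidden
  for (l in seq_along(p$layers)) {
    W <- p$layers[[l]]$W_ih
    inD <- ncol(W) - fbD
    W[, seq_len(inD)] <- base_params$layers[[l]]$W_ih
    W[, inD + seq_len(fbD)] <- 0
    p$layers[[l]]$W_ih <- W
    p$layers[[l]]$b_ih <- base_params$layers[[l]]$b_ih
    p$layers[[l]]$W_hh <- base_params$layers[[l]]$W_hh
    p$layers[[l]]$b_hh <- base_params$layers[[l]]$b_hh
  }
  d <- length(p$fb$b)
  p$fb$W[[d]] <- p$fb$W[[d]] * 0
  p$fb$b[[d]] <- p$fb$b[[d]] * 0
  p$head <- base_params$head
  p
}

# Central finite-difference check of engine gradients at a few random
# coordinates per block; returns the max absolute error.
fd_gradient_error <- function(config, seed = 5L, T_hours = 10L, B = 2L,
                              n_coords = 3L) {
  withr::with_seed(seed, {
    p <- init_params(config, seed = seed + 1L)
    D <- config$input_dim
    X <- array(stats::runif(B * D * T_hours), c(B, D, T_hours))
    fby <- if (config$regression)
      matrix(stats::runif(B * T_hours), B, T_hours)
    else matrix(stats::rbinom(B * T_hours, 1, 0.5), B, T_hours)
    y <- matrix(NA_real_, B, T_hours)
    y[, seq_len(T_hours - 3L)] <- fby[, seq_len(T_hours - 3L)]
    Tlens <- c(T_hours, rep(T_hours - 1L, B - 1L))
    spec <- akiwarn:::make_loss_spec(config, y, Tlens, class_weight = 1.5)
    runf <- function(pp) {
      if (config$has_feedback)
        akiwarn:::sc_batch(pp, config, X, fby, Tlens, loss_spec = spec)
      else
        akiwarn:::baseline_batch(pp, config, X, Tlens, loss_spec = spec)
    }
    res <- if (config$has_feedback)
      akiwarn:::sc_batch(p, config, X, fby, Tlens, loss_spec = spec,
                         grad = TRUE)
    else
      akiwarn:::baseline_batch(p, config, X, Tlens, loss_spec = spec,
                               grad = TRUE)
    flat <- akiwarn:::flatten_params(p)
    gflat <- akiwarn:::flatten_params(res$grads)
    err <- 0
    for (nm in names(flat)) {
      ks <- sample(seq_along(flat[[nm]]),
                   min(n_coords, length(flat[[nm]])))
      for (k in ks) {
        e <- 1e-6
        pp <- flat
        pp[[nm]][k] <- pp[[nm]][k] + e
        lp <- runf(akiwarn:::unflatten_params(pp, p))$loss
        pp[[nm]][k] <- pp[[nm]][k] - 2 * e
        lm <- runf(akiwarn:::unflatten_params(pp, p))$loss
        err <- max(err, abs((lp - lm) / (2 * e) - gflat[[nm]][k]))
      }
    }
    err
  })
}
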