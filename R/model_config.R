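VARIANTS <- c("baseline", "baseline_attention", "self_correcting",
              "self_correcting_reg", "self_correcting_regression_reg")

#' Model configuration
#'
#' Describes one member of the model family: the plain stacked GRU/LSTM
#' baselines (optionally with causal self-attention between layers), the
#' self-correcting network that feeds `(stop_grad(y_hat[t-L]), y[t-L])`
#' through a small feedforward "feedback network" into every recurrent
#' layer, the regularized variant that additionally predicts the next
#' input vector `x_hat[t+1]` (fed back at lag 1, with an MSE penalty of
#' coefficient `lambda` on the loss), and the regression variant that
#' predicts next-6-hour urine output instead of the AKI label.
#'
#' @param input_dim Number of model input features D'.
#' @param variant One of `baseline`, `baseline_attention`,
#'   `self_correcting`, `self_correcting_reg`,
#'   `self_correcting_regression_reg`.
#' @param cell_type `"gru"` (default) or `"lstm"`.
#' @param n_layers Number of recurrent layers (default 2).
#' @param hidden_size Units per recurrent layer (default 128).
#' @param dropout_rate Dropout between layers and before the output head,
#'   disabled at evaluation (default 0.10).
#' @param lag Feedback lag L in hours; equals the prediction horizon
#'   (default 6).
#' @param feedback_hidden Width of the feedback feedforward layers and of
#'   the shared feedback vector (default `hidden_size / 4`).
#' @param feedback_depth Number of feedback dense layers (default 2).
#' @param lambda Coefficient of the input-prediction MSE penalty; 0
#'   disables the regularizer term (default 0.1 for regularized variants).
#' @param stop_gradient Sever backpropagation where the lagged prediction
#'   (and predicted input) enter the feedback network (default `TRUE`).
#' @param attention_causal Causal mask in baseline self-attention
#'   (default `TRUE`; a non-causal switch is provided for comparison).
#' @return An `aki_model_config`.
#' @export
model_config <- function(input_dim,
                         variant = "self_correcting_reg",
                         cell_type = c("gru", "lstm"),
                         n_layers = 2L,
                         hidden_size = 128L,
                         dropout_rate = 0.10,
                         lag = 6L,
                         feedback_hidden = NULL,
                         feedback_depth = 2L,
                         lambda = NULL,
                         stop_gradient = TRUE,
                         attention_causal = TRUE) {
  cell_type <- match.arg(cell_type)
  variant <- match.arg(variant, VARIANTS)
  if (n_layers < 1L) stopf("'n_layers' must be >= 1")
  if (hidden_size < 1L) stopf("'hidden_size' must be >= 1")
  if (lag < 1L) stopf("'lag' must be >= 1")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stopf("'dropout_rate' must lie in [0, 1)")
  regularized <- variant %in% c("self_correcting_reg",
                                "self_correcting_regression_reg")
  lambda <- lambda %||% (if (regularized) 0.1 else 0)
  if (lambda < 0) stopf("'lambda' must be >= 0")
  feedback_hidden <- feedback_hidden %||% max(2L, hidden_size %/% 4L)
  structure(list(
    input_dim = as.integer(input_dim), variant = variant,
    cell_type = cell_type, n_layers = as.integer(n_layers),
    hidden_size = as.integer(hidden_size), dropout_rate = dropout_rate,
    lag = as.integer(lag),
    feedback_hidden = as.integer(feedback_hidden),
    feedback_depth = as.integer(feedback_depth),
    lambda = lambda, stop_gradient = isTRUE(stop_gradient),
    attention_causal = isTRUE(attention_causal),
    has_feedback = variant %in% c("self_correcting", "self_correcting_reg",
                                  "self_correcting_regression_reg"),
    regularized = regularized,
    regression = variant == "self_correcting_regression_reg",
    attention = variant == "baseline_attention"
  ), class = "aki_model_config")
}

n_gates <- function(config) if (config$cell_type == "gru") 3L else 4L

# Feedback-network input width: (y_hat_lag, y_lag) plus, for regularized
# variants, (x_hat_cur, x_cur).
fb_input_dim <- function(config) {
  2L + if (config$regularized) 2L * config$input_dim else 0L
}

layer_input_dim <- function(config, l) {
  base <- if (l == 1L) config$input_dim else config$hidden_size
  base + if (config$has_feedback) config$feedback_hidden else 0L
}

#' Exact trainable-parameter counts per block
#'
#' Recurrent layers follow the two-bias-vector convention (separate
#' input-to-hidden and hidden-to-hidden biases), so a GRU layer with
#' input width `i` and hidden width `h` holds `3h(i + h) + 6h` parameters.
#'
#' @param config An [model_config()].
#' @return Named list of per-block counts plus `total`.
#' @export
count_parameters <- function(config) {
  stopifnot(inherits(config, "aki_model_config"))
  g <- n_gates(config)
  h <- config$hidden_size
  recurrent <- sum(vapply(seq_len(config$n_layers), function(l) {
    i <- layer_input_dim(config, l)
    g * h * i + g * h * h + 2L * g * h
  }, numeric(1)))
  attention <- if (config$attention) config$n_layers * 3L * h * h else 0L
  feedback <- 0L
  if (config$has_feedback) {
    prev <- fb_input_dim(config)
    for (d in seq_len(config$feedback_depth)) {
      feedback <- feedback + config$feedback_hidden * prev +
        config$feedback_hidden
      prev <- config$feedback_hidden
    }
  }
  heads <- h + 1L +
    if (config$regularized) config$input_dim * h + config$input_dim else 0L
  defaults <- if (config$has_feedback)
    2L + if (config$regularized) config$input_dim else 0L else 0L
  out <- list(recurrent = recurrent, attention = attention,
              feedback = feedback, heads = heads, defaults = defaults)
  out$total <- sum(unlist(out))
  out
}

unif_mat <- function(nr, nc, k) matrix(stats::runif(nr * nc, -k, k), nr, nc)

#' Initialize model parameters
#'
#' Recurrent weights and biases are uniform on
#' `[-1/sqrt(hidden), 1/sqrt(hidden)]`; feedback and head layers use their
#' own fan-in.  The trained feedback defaults start at 0.5 (a neutral
#' probability / mid-scale input) and are genuinely trained by
#' backpropagation.  Initial hidden states are zeros and not trained.
#'
#' @param config An [model_config()].
#' @param seed Integer seed.
#' @return Named parameter list (class `aki_params`).
#' @export
init_params <- function(config, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    g <- n_gates(config)
    h <- config$hidden_size
    k <- 1 / sqrt(h)
    layers <- lapply(seq_len(config$n_layers), function(l) {
      i <- layer_input_dim(config, l)
      list(W_ih = unif_mat(g * h, i, k), b_ih = stats::runif(g * h, -k, k),
           W_hh = unif_mat(g * h, h, k), b_hh = stats::runif(g * h, -k, k))
    })
    params <- list(layers = layers)
    if (config$attention) {
      ka <- 1 / sqrt(h)
      params$attn <- lapply(seq_len(config$n_layers), function(l)
        list(Wq = unif_mat(h, h, ka), Wk = unif_mat(h, h, ka),
             Wv = unif_mat(h, h, ka)))
    }
    if (config$has_feedback) {
      prev <- fb_input_dim(config)
      W <- list(); b <- list()
      for (d in seq_len(config$feedback_depth)) {
        kf <- 1 / sqrt(prev)
        W[[d]] <- unif_mat(config$feedback_hidden, prev, kf)
        b[[d]] <- stats::runif(config$feedback_hidden, -kf, kf)
        prev <- config$feedback_hidden
      }
      params$fb <- list(W = W, b = b)
      params$defaults <- list(y_hat = 0.5, y = 0.5)
      if (config$regularized)
        params$defaults$x_hat <- rep(0.5, config$input_dim)
    }
    params$head <- list(w = stats::runif(h, -k, k),
                        b = stats::runif(1, -k, k))
    if (config$regularized)
      params$xhead <- list(W = unif_mat(config$input_dim, h, k),
                           b = stats::runif(config$input_dim, -k, k))
    structure(params, class = "aki_params")
  })
}

# Flatten/unflatten parameter lists for the optimizer and checkpoints.
flatten_params <- function(p) {
  out <- list()
  walk <- function(x, prefix) {
    if (is.list(x)) {
      nms <- names(x) %||% as.character(seq_along(x))
      if (is.null(names(x))) names(x) <- nms
      for (nm in names(x)) walk(x[[nm]], paste0(prefix, "/", nm))
    } else out[[substring(prefix, 2)]] <<- x
  }
  walk(unclass(p), "")
  out
}

set_leaf <- function(p, path, value) {
  keys <- strsplit(path, "/", fixed = TRUE)[[1]]
  assign_rec <- function(x, keys, value) {
    k <- keys[[1]]
    ik <- suppressWarnings(as.integer(k))
    key <- if (!is.na(ik) && identical(as.character(ik), k)) ik else k
    if (length(keys) == 1L) x[[key]] <- value
    else x[[key]] <- assign_rec(x[[key]], keys[-1], value)
    x
  }
  assign_rec(p, keys, value)
}

unflatten_params <- function(flat, template) {
  p <- unclass(template)
  for (nm in names(flat)) {
    leaf <- flat[[nm]]
    old <- flatten_params(template)[[nm]]
    if (!is.null(dim(old))) dim(leaf) <- dim(old)
    p <- set_leaf(p, nm, leaf)
  }
  structure(p, class = "aki_params")
}

#' Save / load a model checkpoint
#'
#' Checkpoints are single self-describing JSON documents holding the
#' config echo and every named parameter block at full precision; loading
#' validates all shapes against the embedded config.
#'
#' @param params `aki_params`.
#' @param config The matching `aki_model_config`.
#' @param path Output path.
#' @param extra Optional named list stored verbatim (e.g. cohort stats
#'   echo, feature names, training log).
#' @return `save_checkpoint()`: invisibly `path`; `load_checkpoint()`:
#'   list with `config`, `params` and any extras.
#' @export
save_checkpoint <- function(params, config, path, extra = list()) {
  flat <- flatten_params(params)
  blocks <- lapply(flat, function(m)
    list(dim = dim(m) %||% length(m), data = as.numeric(m)))
  doc <- c(list(format = "akiwarn-checkpoint-1",
                config = unclass(config), blocks = blocks), extra)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "akiwarn-checkpoint-1"))
    stopf("%s is not an akiwarn checkpoint", path)
  cfgl <- doc$config
  config <- do.call(model_config, cfgl[c(
    "input_dim", "variant", "cell_type", "n_layers", "hidden_size",
    "dropout_rate", "lag", "feedback_hidden", "feedback_depth", "lambda",
    "stop_gradient", "attention_causal")])
  template <- init_params(config, seed = 0L)
  tflat <- flatten_params(template)
  flat <- list()
  for (nm in names(tflat)) {
    blk <- doc$blocks[[nm]]
    if (is.null(blk))
      stopf("checkpoint %s lacks parameter block '%s'", path, nm)
    v <- as.numeric(blk$data)
    want <- dim(tflat[[nm]]) %||% length(tflat[[nm]])
    got <- as.integer(blk$dim)
    if (!identical(as.integer(want), got) || length(v) != prod(got))
      stopf("checkpoint block '%s' has shape [%s], expected [%s]",
            nm, paste(got, collapse = "x"),
            paste(as.integer(want), collapse = "x"))
    if (!is.null(dim(tflat[[nm]]))) dim(v) <- dim(tflat[[nm]])
    flat[[nm]] <- v
  }
  out <- list(config = config, params = unflatten_params(flat, template))
  extras <- setdiff(names(doc), c("format", "config", "blocks"))
  out[extras] <- doc[extras]
  out
}
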