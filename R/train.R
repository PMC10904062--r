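#' Training configuration
#'
#' @param learning_rate Initial Adam learning rate (default 1e-3).
#' @param decay Multiplicative per-epoch learning-rate decay (default
#'   0.98).
#' @param grad_clip_norm Global gradient-norm clip (default 1.0).
#' @param epochs Maximum epochs.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement); training "until convergence" is realized as early
#'   stopping when a validation split is available.
#' @param val_fraction Fraction of training stays held out for early
#'   stopping (0 disables early stopping).
#' @param class_weight_mode `"auto"` (positive-class weight =
#'   negatives/positives over the training labels) or `"fixed"`.
#' @param class_weight Weight used when `class_weight_mode = "fixed"`.
#' @param folds Cross-validation folds (default 5).
#' @param batch_size Stays per batch (length-bucketed, padded).
#' @param eval_threshold Probability threshold for F1 (default 0.5).
#' @param seed Integer seed controlling initialization, batching,
#'   dropout, and fold assignment.
#' @return An `aki_train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, decay = 0.98,
                         grad_clip_norm = 1.0, epochs = 20L,
                         patience = 5L, val_fraction = 0.1,
                         class_weight_mode = c("auto", "fixed"),
                         class_weight = 1, folds = 5L,
                         batch_size = 64L, eval_threshold = 0.5,
                         seed = 1L) {
  class_weight_mode <- match.arg(class_weight_mode)
  if (learning_rate <= 0) stopf("'learning_rate' must be > 0")
  if (folds < 2L) stopf("'folds' must be >= 2")
  structure(list(
    learning_rate = learning_rate, decay = decay,
    grad_clip_norm = grad_clip_norm, epochs = as.integer(epochs),
    patience = as.integer(patience), val_fraction = val_fraction,
    class_weight_mode = class_weight_mode, class_weight = class_weight,
    folds = as.integer(folds), batch_size = as.integer(batch_size),
    eval_threshold = eval_threshold, seed = as.integer(seed)
  ), class = "aki_train_config")
}

#' Positive-class weight from training labels
#'
#' @param y Pooled 0/1 training labels (NAs ignored).
#' @return `(# negatives) / (# positives)`, applied to the positive terms
#'   of the cross-entropy.
#' @export
class_weights <- function(y) {
  y <- y[is.finite(y)]
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos == 0L || n_neg == 0L)
    stopf("training labels contain a single class")
  n_neg / n_pos
}

#' Total training loss for one stay
#'
#' Classification: mean over defined-label steps of weighted
#' cross-entropy (positive terms scaled by `class_weight`).  Regression:
#' mean squared error on the scaled urine target.  Regularized variants
#' add `lambda / D` times the mean squared input-prediction error over
#' the steps where the model produced a prediction (`t >= 2`).
#'
#' @param y_hat Predictions (probabilities or regression outputs),
#'   length T.
#' @param y Targets with NA at undefined steps.
#' @param x_hat Optional (T+1) x D input predictions (row t = prediction
#'   for hour t) as returned by [forward_stay()].
#' @param x Optional T x D actual inputs.
#' @param lambda Regularizer coefficient.
#' @param class_weight Positive-class weight.
#' @param type `"classification"` or `"regression"`.
#' @return Scalar loss.
#' @export
total_loss <- function(y_hat, y, x_hat = NULL, x = NULL, lambda = 0,
                       class_weight = 1, type = "classification") {
  if (length(y_hat) != length(y))
    stopf("y_hat and y differ in length")
  def <- is.finite(y)
  if (!any(def)) stopf("no defined labels")
  lab <- if (type == "regression") {
    mean((y_hat[def] - y[def])^2)
  } else {
    p <- pmin(pmax(y_hat[def], 1e-12), 1 - 1e-12)
    yy <- y[def]
    w <- ifelse(yy == 1, class_weight, 1)
    mean(-w * (yy * log(p) + (1 - yy) * log1p(-p)))
  }
  reg <- 0
  if (lambda > 0 && !is.null(x_hat)) {
    T_hours <- nrow(x)
    if (T_hours >= 2L) {
      dd <- x_hat[2:T_hours, , drop = FALSE] - x[2:T_hours, , drop = FALSE]
      reg <- lambda * mean(rowSums(dd * dd)) / ncol(x)
    }
  }
  lab + reg
}

# ---- batching ---------------------------------------------------------

# Length-bucketed padded batches from prepared stays.
build_batches <- function(prep, batch_size, regression = FALSE) {
  Ts <- vapply(prep, `[[`, numeric(1), "T_hours")
  ord <- order(Ts)
  chunks <- split(ord, ceiling(seq_along(ord) / batch_size))
  lapply(chunks, function(idx) {
    stays <- prep[idx]
    B <- length(stays)
    T_max <- max(vapply(stays, `[[`, numeric(1), "T_hours"))
    D <- ncol(stays[[1]]$features)
    X <- array(0, c(B, D, T_max))
    y <- matrix(NA_real_, B, T_max)
    yclass <- matrix(NA_real_, B, T_max)
    ve <- matrix(0, B, T_max)
    Tlens <- integer(B)
    for (b in seq_len(B)) {
      s <- stays[[b]]
      Tb <- s$T_hours
      X[b, , seq_len(Tb)] <- t(s$features)
      y[b, seq_len(Tb)] <- if (regression) s$Ytilde else s$y
      yclass[b, seq_len(Tb)] <- s$y
      ve[b, seq_len(Tb)] <- s$valid_eval
      Tlens[b] <- Tb
    }
    list(X = X, y = y, yclass = yclass, fby = ifelse(is.na(y), 0, y),
         valid_eval = ve, Tlens = Tlens, stay_ids = names(stays),
         weights = vapply(stays, `[[`, numeric(1), "weight"))
  })
}

run_batch <- function(params, config, batch, loss_spec = NULL,
                      grad = FALSE, train = FALSE) {
  if (config$has_feedback)
    sc_batch(params, config, batch$X, batch$fby, batch$Tlens,
             loss_spec = loss_spec, grad = grad, train = train)
  else
    baseline_batch(params, config, batch$X, batch$Tlens,
                   loss_spec = loss_spec, grad = grad, train = train)
}

# ---- Adam -------------------------------------------------------------

adam_init <- function(params) {
  flat <- flatten_params(params)
  list(m = lapply(flat, function(x) x * 0),
       v = lapply(flat, function(x) x * 0), t = 0L)
}

global_grad_norm <- function(gflat)
  sqrt(sum(vapply(gflat, function(g) sum(g * g), numeric(1))))

adam_step <- function(params, grads, state, lr, clip = 1.0,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  pflat <- flatten_params(params)
  gflat <- flatten_params(grads)
  gnorm <- global_grad_norm(gflat)
  if (is.finite(clip) && clip > 0 && gnorm > clip)
    gflat <- lapply(gflat, function(g) g * (clip / gnorm))
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(pflat)) {
    g <- gflat[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    pflat[[nm]] <- pflat[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = unflatten_params(pflat, params), state = state,
       grad_norm = gnorm)
}

# ---- training ---------------------------------------------------------

#' Train one model on prepared stays
#'
#' Adam with per-epoch learning-rate decay, global-norm gradient
#' clipping, dropout, and a reweighted cross-entropy for the imbalanced
#' labels.  When a validation split is available (`val_fraction > 0` or
#' `val` supplied), training stops once the validation loss has not
#' improved for `patience` epochs and the best parameters are kept.
#'
#' @param prep Prepared stays from [prepare_stays()].
#' @param config An [model_config()].
#' @param tcfg An [train_config()].
#' @param val Optional prepared validation stays (overrides
#'   `val_fraction`).
#' @param verbose Print per-epoch losses.
#' @return An `aki_fit`: list with `params`, `config`, `tcfg`,
#'   `class_weight`, `log` (per-epoch data.frame), `converged`.
#' @export
train_model <- function(prep, config, tcfg, val = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "aki_model_config"),
            inherits(tcfg, "aki_train_config"))
  D <- ncol(prep[[1]]$features)
  if (config$input_dim != D)
    stopf("config input_dim (%d) does not match features (%d)",
          config$input_dim, D)
  withr::with_seed(tcfg$seed, {
    if (is.null(val) && tcfg$val_fraction > 0 && length(prep) >= 10L) {
      n_val <- max(1L, floor(tcfg$val_fraction * length(prep)))
      vidx <- sample(seq_along(prep), n_val)
      val <- prep[vidx]
      prep <- prep[-vidx]
    }
    cw <- if (config$regression) 1
      else if (tcfg$class_weight_mode == "auto")
        class_weights(unlist(lapply(prep, `[[`, "y")))
      else tcfg$class_weight
    batches <- build_batches(prep, tcfg$batch_size, config$regression)
    specs <- lapply(batches, function(b)
      make_loss_spec(config, b$y, b$Tlens, cw))
    val_batches <- if (!is.null(val)) {
      vb <- build_batches(val, tcfg$batch_size, config$regression)
      list(batches = vb,
           specs = lapply(vb, function(b)
             make_loss_spec(config, b$y, b$Tlens, cw)))
    }
    params <- init_params(config, seed = sample.int(2^30, 1))
    state <- adam_init(params)
    log <- data.frame()
    best_val <- Inf; best_params <- params; stall <- 0L
    converged <- FALSE
    for (epoch in seq_len(tcfg$epochs)) {
      lr <- tcfg$learning_rate * tcfg$decay^(epoch - 1L)
      ord <- sample(seq_along(batches))
      tot <- 0; totreg <- 0; nstays <- 0; gn <- 0
      for (i in ord) {
        res <- run_batch(params, config, batches[[i]], specs[[i]],
                         grad = TRUE, train = TRUE)
        if (!is.finite(res$loss))
          stopf("training diverged (non-finite loss) at epoch %d", epoch)
        up <- adam_step(params, res$grads, state, lr,
                        clip = tcfg$grad_clip_norm)
        params <- up$params; state <- up$state
        B <- length(batches[[i]]$Tlens)
        tot <- tot + res$loss * B
        totreg <- totreg + (res$reg_loss %||% 0) * B
        nstays <- nstays + B
        gn <- max(gn, up$grad_norm)
      }
      train_loss <- tot / nstays
      val_loss <- NA_real_
      if (!is.null(val_batches)) {
        vl <- 0; vn <- 0
        for (i in seq_along(val_batches$batches)) {
          r <- run_batch(params, config, val_batches$batches[[i]],
                         val_batches$specs[[i]])
          B <- length(val_batches$batches[[i]]$Tlens)
          vl <- vl + r$loss * B; vn <- vn + B
        }
        val_loss <- vl / vn
      }
      log <- rbind(log, data.frame(
        epoch = epoch, train_loss = train_loss, val_loss = val_loss,
        reg_loss = totreg / nstays, max_grad_norm = gn, lr = lr))
      if (verbose)
        message(sprintf("epoch %d: train %.4f val %.4f", epoch,
                        train_loss, val_loss))
      if (!is.null(val_batches)) {
        if (val_loss < best_val - 1e-6) {
          best_val <- val_loss; best_params <- params; stall <- 0L
        } else {
          stall <- stall + 1L
          if (stall >= tcfg$patience) { converged <- TRUE; break }
        }
      }
    }
    if (!is.null(val_batches)) params <- best_params
    structure(list(params = params, config = config, tcfg = tcfg,
                   class_weight = cw, log = log, converged = converged),
              class = "aki_fit")
  })
}

#' Pooled predictions over prepared stays
#'
#' @param fit An `aki_fit` (or list with `params` and `config`).
#' @param prep Prepared stays.
#' @return data.frame with one row per (stay, hour): `stay_id`, `hour`,
#'   `score` (risk score: probability for classification, `0.5 -`
#'   predicted mean rate for the regression variant), `y`, `valid_eval`.
#' @export
predict_stays <- function(fit, prep) {
  config <- fit$config
  batches <- build_batches(prep, 64L, config$regression)
  rows <- list()
  for (bt in batches) {
    res <- run_batch(fit$params, config, bt)
    for (b in seq_along(bt$Tlens)) {
      Tb <- bt$Tlens[b]
      raw <- res$y_hat[b, seq_len(Tb)]
      score <- if (config$regression) 0.5 - raw else raw
      id <- bt$stay_ids[b]
      yb <- bt$yclass[b, seq_len(Tb)]
      rows[[length(rows) + 1L]] <- data.frame(
        stay_id = id, hour = seq_len(Tb), score = score, y = yb,
        valid_eval = bt$valid_eval[b, seq_len(Tb)])
    }
  }
  do.call(rbind, rows)
}

#' Evaluate pooled AUC / F1 on the evaluable steps
#'
#' Metrics are pooled over all (stay, hour) pairs with `valid_eval = 1`
#' (hour > horizon and defined label); other steps never enter.
#'
#' @param fit An `aki_fit`.
#' @param prep Prepared stays.
#' @param threshold F1 threshold on the probability (classification); the
#'   regression variant is scored with the strict implied-rate rule.
#' @return List `auc`, `f1`, `n`, `prevalence` (AUC is NA with a warning
#'   if the evaluable steps hold a single class).
#' @export
evaluate_model <- function(fit, prep, threshold = 0.5) {
  pr <- predict_stays(fit, prep)
  pr <- pr[pr$valid_eval == 1 & is.finite(pr$y), , drop = FALSE]
  out <- list(n = nrow(pr), prevalence = mean(pr$y))
  if (length(unique(pr$y)) < 2L) {
    warning("evaluation steps contain a single class; AUC undefined",
            call. = FALSE)
    out$auc <- NA_real_
    out$f1 <- NA_real_
    return(out)
  }
  pred_pos <- if (fit$config$regression) as.numeric(pr$score > 0)
    else as.numeric(pr$score >= threshold)
  out$auc <- roc_auc(pr$score, pr$y)
  out$f1 <- f1_score(pred_pos, pr$y, threshold = 0.5)
  out
}

#' Seeded stay-level fold assignment
#'
#' @param ids Stay ids.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return List of k character vectors partitioning `ids`.
#' @export
make_folds <- function(ids, k, seed = 1L) {
  if (length(ids) < k) stopf("need at least %d stays for %d folds", k, k)
  withr::with_seed(as.integer(seed), {
    shuffled <- sample(ids)
    split(shuffled, rep_len(seq_len(k), length(shuffled)))
  })
}

#' Stay-level k-fold cross-validation
#'
#' Stays (never time steps) are partitioned by a seeded shuffle.  For
#' each fold, normalization statistics are fitted on the training folds
#' only, the model is trained there, and the held-out stays are scored at
#' their evaluable steps.  Stats provenance is asserted against the
#' held-out ids, so evaluation data can never leak into the cohort
#' statistics.
#'
#' @param cohort An `aki_cohort` from [build_cohort()].
#' @param config An [model_config()] (its `input_dim` must match the
#'   assembled feature count).
#' @param tcfg An [train_config()].
#' @param folds Optional precomputed fold assignment (from
#'   [make_folds()]); defaults to `make_folds(ids, tcfg$folds,
#'   tcfg$seed)`.
#' @param pooled_stats Fit normalization statistics on all stays instead
#'   of the training folds (matches pooling statistics "in the cohort";
#'   default `FALSE` to avoid evaluation leakage).
#' @param fold_data Optional precomputed per-fold prepared data from
#'   [make_fold_data()] (lets several configs share one preprocessing
#'   pass); must match `folds`.
#' @return List with `fold_results` (per fold: `fold`, `auc`, `f1`, `n`,
#'   `train_auc`, `gap`, `converged`, `test_ids`, `predictions`),
#'   `pooled` (`auc`, `f1`, `n` over all held-out predictions), `folds`.
#' @export
cross_validate <- function(cohort, config, tcfg, folds = NULL,
                           pooled_stats = FALSE, fold_data = NULL) {
  stopifnot(inherits(cohort, "aki_cohort"))
  ids <- vapply(cohort$hourly, `[[`, "", "stay_id")
  folds <- folds %||% make_folds(ids, tcfg$folds, tcfg$seed)
  fold_data <- fold_data %||% make_fold_data(cohort, folds, pooled_stats)
  fold_results <- list()
  pooled_rows <- list()
  for (k in seq_along(folds)) {
    test_ids <- folds[[k]]
    prep_tr <- fold_data[[k]]$train
    prep_te <- fold_data[[k]]$test
    fit <- train_model(prep_tr, config, tcfg)
    ev <- evaluate_model(fit, prep_te, threshold = tcfg$eval_threshold)
    ev_tr <- evaluate_model(fit, prep_tr, threshold = tcfg$eval_threshold)
    pr <- predict_stays(fit, prep_te)
    pr <- pr[pr$valid_eval == 1 & is.finite(pr$y), , drop = FALSE]
    pooled_rows[[k]] <- pr
    fold_results[[k]] <- list(
      fold = k, auc = ev$auc, f1 = ev$f1, n = ev$n,
      train_auc = ev_tr$auc, gap = ev_tr$auc - ev$auc,
      converged = fit$converged, test_ids = test_ids, predictions = pr)
  }
  pooled <- do.call(rbind, pooled_rows)
  pooled_metrics <- list(
    auc = if (length(unique(pooled$y)) > 1L)
      roc_auc(pooled$score, pooled$y) else NA_real_,
    f1 = if (config$regression)
      f1_score(as.numeric(pooled$score > 0), pooled$y, 0.5)
    else f1_score(pooled$score, pooled$y, tcfg$eval_threshold),
    n = nrow(pooled))
  list(fold_results = fold_results, pooled = pooled_metrics,
       folds = folds)
}

#' Precompute per-fold normalization and prepared stays
#'
#' For each fold, fits cohort statistics on the training folds only
#' (asserting that the provenance excludes the held-out stays) and
#' prepares both splits.  Useful when several configurations are
#' cross-validated under the same fold assignment.
#'
#' @param cohort An `aki_cohort`.
#' @param folds Fold assignment from [make_folds()].
#' @param pooled_stats Fit statistics on all stays instead (leaky;
#'   matches pooling "in the cohort").
#' @return List (per fold) of `list(train, test)` prepared-stay lists.
#' @export
make_fold_data <- function(cohort, folds, pooled_stats = FALSE) {
  ids <- vapply(cohort$hourly, `[[`, "", "stay_id")
  all_stats <- if (pooled_stats)
    fit_cohort_stats(cohort$hourly, cohort$statics)
  lapply(seq_along(folds), function(k) {
    test_ids <- folds[[k]]
    train_ids <- setdiff(ids, test_ids)
    stats <- if (pooled_stats) all_stats else {
      tr_idx <- match(train_ids, ids)
      fit_cohort_stats(cohort$hourly[tr_idx],
                       cohort$statics[match(train_ids,
                                            cohort$statics$stay_id), ,
                                      drop = FALSE])
    }
    if (!pooled_stats && length(intersect(stats$provenance, test_ids)))
      stopf("cohort stats provenance overlaps held-out stays")
    list(train = prepare_stays(cohort, stats, train_ids),
         test = prepare_stays(cohort, stats, test_ids),
         stats = stats)
  })
}

#' Train and compare several model configurations
#'
#' Every configuration is cross-validated under identical fold
#' assignments for each seed, so differences reflect the architectures
#' rather than the splits.  Per-run failures are recorded and the
#' comparison continues.
#'
#' @param cohort An `aki_cohort`.
#' @param configs Named list of [model_config()]s (>= 2 for a
#'   comparison; a single config yields a one-row report).
#' @param tcfg An [train_config()]; seeds are `tcfg$seed + 0:(n_seeds-1)`.
#' @param n_seeds Number of training seeds per configuration.
#' @return An `aki_metrics_report`: list with `runs` (data.frame: model,
#'   seed, pooled auc/f1, mean fold gap), `summary` (per-model mean/SD),
#'   `fold_results`, `errors`.
#' @export
compare_models <- function(cohort, configs, tcfg, n_seeds = 1L) {
  stopifnot(length(configs) >= 1L, !is.null(names(configs)))
  ids <- vapply(cohort$hourly, `[[`, "", "stay_id")
  runs <- data.frame()
  fold_results <- list()
  errors <- list()
  for (s in seq_len(n_seeds)) {
    seed_s <- tcfg$seed + s - 1L
    folds <- make_folds(ids, tcfg$folds, seed_s)
    fold_data <- make_fold_data(cohort, folds)
    tcfg_s <- tcfg; tcfg_s$seed <- seed_s
    for (nm in names(configs)) {
      res <- tryCatch(
        cross_validate(cohort, configs[[nm]], tcfg_s, folds = folds,
                       fold_data = fold_data),
        error = function(e) e)
      if (inherits(res, "error")) {
        errors[[paste(nm, s, sep = "/")]] <- conditionMessage(res)
        next
      }
      gaps <- vapply(res$fold_results, `[[`, numeric(1), "gap")
      runs <- rbind(runs, data.frame(
        model = nm, seed = seed_s, auc = res$pooled$auc,
        f1 = res$pooled$f1, n = res$pooled$n,
        gap = mean(gaps, na.rm = TRUE)))
      fold_results[[paste(nm, s, sep = "/")]] <- res$fold_results
    }
  }
  summary <- do.call(rbind, lapply(split(runs, runs$model), function(d)
    data.frame(model = d$model[1],
               auc_mean = mean(d$auc), auc_sd = stats::sd(d$auc),
               f1_mean = mean(d$f1), f1_sd = stats::sd(d$f1),
               gap_mean = mean(d$gap), gap_sd = stats::sd(d$gap),
               n_runs = nrow(d))))
  rownames(summary) <- NULL
  structure(list(runs = runs, summary = summary,
                 fold_results = fold_results, errors = errors),
            class = "aki_metrics_report")
}

#' Gradient audit of the feedback loop
#'
#' On a small synthetic stay, measures the gradient of the summed future
#' losses (steps `>= t0 + lag`) with respect to the prediction made at
#' `t0`, with the stop-gradient rule on and off, and cross-checks the
#' off-mode value against a central finite difference obtained by
#' perturbing the lagged prediction where it enters the feedback network.
#' With stop-gradient on the feedback path is severed, so the future
#' losses contribute exactly zero; the local loss derivative at `t0` is
#' identical in both modes.
#'
#' @param config An [model_config()] for a self-correcting variant.
#' @param T_hours Stay length (must satisfy `T_hours >= 2 * lag + 1`).
#' @param t0 Audited step (default `lag + 1`).
#' @param seed Seed for the synthetic stay and the parameters.
#' @param param_scale Scale of the uniform parameter draw (a moderately
#'   large value makes the feedback path visibly active).
#' @param fd_eps Finite-difference step.
#' @return List with `grad_future_on`, `grad_future_off`, `fd_off`,
#'   `local_grad` and the audit metadata.
#' @export
gradient_audit <- function(config, T_hours = 8L, t0 = NULL, seed = 1L,
                           param_scale = 1.0, fd_eps = 1e-5) {
  stopifnot(config$has_feedback)
  L <- config$lag
  if (T_hours < 2L * L + 1L)
    stopf("gradient audit needs T_hours >= 2*lag + 1")
  t0 <- t0 %||% (L + 1L)
  if (t0 + L > T_hours) stopf("t0 + lag exceeds T_hours")
  cfg_eval <- config; cfg_eval$dropout_rate <- 0
  withr::with_seed(as.integer(seed), {
    params <- init_params(cfg_eval, seed = sample.int(2^30, 1))
    flat <- flatten_params(params)
    flat <- lapply(flat, function(x)
      if (length(x)) array(stats::runif(length(x), -param_scale,
                                        param_scale),
                           dim = dim(x) %||% length(x)) else x)
    params <- unflatten_params(flat, params)
    params$defaults$y_hat <- 0.5; params$defaults$y <- 0.5
    D <- cfg_eval$input_dim
    X <- array(stats::runif(D * T_hours), c(1L, D, T_hours))
    fby <- matrix(stats::rbinom(T_hours, 1L, 0.5), 1L, T_hours)
  })
  future <- seq(t0 + L, T_hours)
  y <- matrix(NA_real_, 1L, T_hours)
  y[1, future] <- fby[1, future]
  spec <- make_loss_spec(cfg_eval, y, T_hours, class_weight = 1)

  run <- function(sg, inject = NULL, grad = FALSE) {
    cfg <- cfg_eval; cfg$stop_gradient <- sg
    sc_batch(params, cfg, X, fby, Tlens = T_hours, loss_spec = spec,
             grad = grad, inject = inject)
  }
  on_res <- run(TRUE, grad = TRUE)
  off_res <- run(FALSE, grad = TRUE)
  g_on <- on_res$dyhat_feedback[1, t0]
  g_off <- off_res$dyhat_feedback[1, t0]
  lp <- run(TRUE, inject = list(step = t0 + L, eps = fd_eps))$loss
  lm <- run(TRUE, inject = list(step = t0 + L, eps = -fd_eps))$loss
  fd <- (lp - lm) / (2 * fd_eps)
  # local loss derivative dJ_t0/dyhat_t0 (value space); mode-independent
  y_loc <- matrix(NA_real_, 1L, T_hours); y_loc[1, t0] <- fby[1, t0]
  spec_loc <- make_loss_spec(cfg_eval, y_loc, T_hours)
  p0 <- on_res$y_hat[1, t0]
  local_grad <- if (cfg_eval$regression)
    2 * spec_loc$M[1, t0] * (p0 - y_loc[1, t0])
  else
    spec_loc$M[1, t0] * (-y_loc[1, t0] / p0 +
                           (1 - y_loc[1, t0]) / (1 - p0))
  list(t0 = t0, lag = L, T_hours = T_hours,
       grad_future_on = g_on, grad_future_off = g_off, fd_off = fd,
       abs_err_fd = abs(g_off - fd), local_grad = local_grad)
}
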