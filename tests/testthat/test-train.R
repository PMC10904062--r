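test_that("class weight is the negative/positive ratio", {
  expect_equal(class_weights(c(rep(0, 90), rep(1, 10))), 9)
  expect_equal(class_weights(c(rep(0, 5), rep(1, 5))), 1)
  expect_equal(class_weights(c(NA, rep(0, 4), rep(1, 2))), 2)
  expect_error(class_weights(rep(1, 10)), "single class")
})

test_that("total loss has its closed-form values and additivity", {
  y <- c(1, 0, NA)
  expect_lt(total_loss(c(1 - 1e-9, 1e-9, 0.5), y), 1e-6)
  expect_equal(total_loss(c(0.5, 0.5, 0.9), c(1, NA, NA)), log(2))
  # weighted: positive term scaled
  expect_equal(total_loss(c(0.5, 0.5, NA_real_), c(1, 0, NA),
                          class_weight = 3),
               (3 * log(2) + log(2)) / 2)
  # balanced set: weighting with 1 equals the unweighted loss
  p <- c(0.2, 0.9, 0.4, 0.7); yy <- c(0, 1, 1, 0)
  expect_equal(total_loss(p, yy, class_weight = 1), total_loss(p, yy))
  # regularizer strictly increases the loss when x_hat != x
  x <- matrix(stats::runif(12), 4, 3)
  xh <- rbind(rep(0.5, 3), x + 0.3)  # rows 2..4 wrong, row 1 = default
  l0 <- total_loss(p, yy, x_hat = xh, x = x, lambda = 0)
  l1 <- total_loss(p, yy, x_hat = xh, x = x, lambda = 0.5)
  expect_gt(l1, l0)
  expect_equal(l1 - l0, 0.5 * mean(rowSums((xh[2:4, ] - x[2:4, ])^2)) / 3)
  expect_error(total_loss(c(0.5), c(1, 0)), "length")
})

test_that("the engine loss equals the mean of per-stay total losses", {
  cfg <- model_config(4, variant = "self_correcting_reg", n_layers = 1,
                      hidden_size = 4, dropout_rate = 0, lag = 2,
                      lambda = 0.3)
  withr::with_seed(14, {
    p <- init_params(cfg, seed = 3)
    Tlens <- c(9L, 7L)
    T_max <- max(Tlens); D <- 4
    X <- array(0, c(2, D, T_max))
    y <- matrix(NA_real_, 2, T_max)
    for (b in 1:2) {
      X[b, , seq_len(Tlens[b])] <- t(matrix(stats::runif(Tlens[b] * D),
                                            Tlens[b], D))
      y[b, seq_len(Tlens[b] - 2L)] <- stats::rbinom(Tlens[b] - 2L, 1, 0.5)
    }
    fby <- ifelse(is.na(y), 0, y)
    cw <- 2.5
    spec <- akiwarn:::make_loss_spec(cfg, y, Tlens, class_weight = cw)
    res <- akiwarn:::sc_batch(p, cfg, X, fby, Tlens, loss_spec = spec)
    per_stay <- vapply(1:2, function(b) {
      Tb <- Tlens[b]
      feats <- t(matrix(X[b, , seq_len(Tb)], D, Tb))
      fs <- forward_stay(feats, fby[b, seq_len(Tb)], cfg, p)
      total_loss(fs$y_hat, y[b, seq_len(Tb)],
                 x_hat = fs$x_hat[seq_len(Tb + 1), , drop = FALSE],
                 x = feats, lambda = cfg$lambda, class_weight = cw)
    }, numeric(1))
    expect_equal(res$loss, mean(per_stay), tolerance = 1e-10)
  })
})

test_that("AUC matches hand-counted concordance and tie conventions", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(roc_auc(c(1, 2, 3, 10), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(rep(0.3, 10), rep(0:1, 5)), 0.5)
  expect_error(roc_auc(1:3, c(1, 1, 1)), "both classes")
  skip_if_not_installed("pROC")
  withr::with_seed(2, {
    for (i in 1:10) {
      s <- stats::runif(50); l <- stats::rbinom(50, 1, 0.4)
      if (length(unique(l)) < 2) next
      expect_equal(roc_auc(s, l),
                   as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                                  direction = "<"))))
    }
  })
})

test_that("F1 matches the confusion-table closed form", {
  # TP=3 FP=1 FN=2 -> precision 0.75, recall 0.6, F1 = 2/3
  labels <- c(1, 1, 1, 0, 1, 1, 0, 0)
  scores <- c(1, 1, 1, 1, 0, 0, 0, 0)
  expect_equal(f1_score(scores, labels), 2 / 3)
  expect_equal(f1_score(labels, labels), 1)
  expect_equal(f1_score(rep(0, 8), labels), 0)
})

test_that("training reduces the loss deterministically per seed", {
  coh <- small_cohort(n = 40, seed = 55, max_hours = 30)
  stats <- fit_cohort_stats(coh$hourly, coh$statics)
  prep <- prepare_stays(coh, stats)
  D <- ncol(prep[[1]]$features)
  cfg <- model_config(D, variant = "self_correcting_reg", n_layers = 1,
                      hidden_size = 8, lambda = 0.1)
  tcfg <- train_config(epochs = 3, learning_rate = 3e-3, batch_size = 16,
                       seed = 5, val_fraction = 0)
  fit1 <- train_model(prep, cfg, tcfg)
  expect_lt(fit1$log$train_loss[3], fit1$log$train_loss[1])
  expect_true(all(fit1$log$reg_loss > 0))   # x-hat MSE component active
  fit2 <- train_model(prep, cfg, tcfg)
  expect_identical(akiwarn:::flatten_params(fit1$params),
                   akiwarn:::flatten_params(fit2$params))
  # a different seed moves the parameters
  tcfg3 <- tcfg; tcfg3$seed <- 6L
  fit3 <- train_model(prep, cfg, tcfg3)
  expect_false(identical(akiwarn:::flatten_params(fit1$params),
                         akiwarn:::flatten_params(fit3$params)))
})

test_that("metrics are computed only over evaluable steps", {
  coh <- small_cohort(n = 15, seed = 77, max_hours = 30, injury_rate = 0.2)
  stats <- fit_cohort_stats(coh$hourly, coh$statics)
  prep <- prepare_stays(coh, stats)
  D <- ncol(prep[[1]]$features)
  cfg <- model_config(D, variant = "baseline", n_layers = 1,
                      hidden_size = 4)
  fit <- structure(list(params = init_params(cfg, 3), config = cfg),
                   class = "aki_fit")
  ev <- evaluate_model(fit, prep)
  pr <- predict_stays(fit, prep)
  keep <- pr$valid_eval == 1 & is.finite(pr$y)
  expect_true(all(pr$hour[keep] > 6))
  expect_equal(ev$n, sum(keep))
  expect_equal(ev$auc, roc_auc(pr$score[keep], pr$y[keep]))
})

test_that("folds partition stays and predictions cover each exactly once", {
  coh <- small_cohort(n = 15, seed = 91, max_hours = 30, injury_rate = 0.2)
  ids <- vapply(coh$hourly, `[[`, "", "stay_id")
  folds <- make_folds(ids, 5, seed = 2)
  expect_setequal(unlist(folds), ids)
  expect_equal(sum(lengths(folds)), length(ids))

  D <- ncol(prepare_stays(coh, fit_cohort_stats(coh$hourly,
                                                coh$statics))[[1]]$features)
  cfg <- model_config(D, variant = "self_correcting", n_layers = 1,
                      hidden_size = 4)
  tcfg <- train_config(epochs = 1, folds = 5, batch_size = 8, seed = 2,
                       val_fraction = 0)
  # small cohort: some folds are single-class and must be reported (NA
  # AUC with a warning), never silently skipped
  expect_warning(cv <- cross_validate(coh, cfg, tcfg, folds = folds),
                 "single class")
  held_out <- unlist(lapply(cv$fold_results, `[[`, "test_ids"))
  expect_setequal(held_out, ids)
  pred_ids <- unique(unlist(lapply(cv$fold_results, function(f)
    unique(f$predictions$stay_id))))
  expect_setequal(pred_ids, ids)
  expect_length(cv$fold_results, 5)
  expect_true(all(vapply(cv$fold_results, function(f)
    is.na(f$auc) || (f$auc >= 0 && f$auc <= 1), logical(1))))
})

test_that("model comparison is reproducible and aggregates its own runs", {
  coh <- small_cohort(n = 15, seed = 13, max_hours = 30, injury_rate = 0.2)
  D <- ncol(prepare_stays(coh, fit_cohort_stats(coh$hourly,
                                                coh$statics))[[1]]$features)
  cfgs <- list(
    a = model_config(D, variant = "baseline", n_layers = 1,
                     hidden_size = 4),
    b = model_config(D, variant = "baseline", n_layers = 1,
                     hidden_size = 4))
  tcfg <- train_config(epochs = 1, folds = 3, batch_size = 8, seed = 4,
                       val_fraction = 0)
  rep1 <- compare_models(coh, cfgs, tcfg, n_seeds = 2)
  expect_equal(nrow(rep1$runs), 4)   # configs x seeds
  # identical configs under shared folds/seeds give identical metrics
  a <- rep1$runs[rep1$runs$model == "a", ]
  b <- rep1$runs[rep1$runs$model == "b", ]
  expect_equal(a$auc, b$auc)
  expect_equal(a$f1, b$f1)
  # summary rows recompute from stored runs
  expect_equal(rep1$summary$auc_mean[rep1$summary$model == "a"],
               mean(a$auc))
  expect_equal(rep1$summary$n_runs, c(2, 2))
})

test_that("gradient audit separates the two backpropagation modes", {
  cfg <- model_config(5, variant = "self_correcting_reg", n_layers = 1,
                      hidden_size = 4, dropout_rate = 0, lag = 2,
                      lambda = 0.1)
  aud <- gradient_audit(cfg, T_hours = 9, seed = 3)
  expect_lt(abs(aud$grad_future_on), 1e-6)
  expect_gt(abs(aud$grad_future_off), 0)
  expect_lt(aud$abs_err_fd, 1e-6)
  expect_equal(aud$t0, 3)
})
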