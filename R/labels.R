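#' Urine-output rate in mL/kg/h
#'
#' @param urine Hourly urine output series (mL/h), raw (pre-normalization)
#'   values on the imputed hourly grid.
#' @param weight Patient weight in kg (> 0).
#' @return Numeric series `urine / weight`.
#' @export
urine_rate <- function(urine, weight) {
  if (!is.finite(weight) || weight <= 0) stopf("'weight' must be > 0")
  urine / weight
}

#' AKI onset under the urine-output RIFLE criterion
#'
#' Hour `t` is an onset hour when the rate has been strictly below
#' 0.5 mL/kg/h for each of the 6 consecutive hours `t-5, ..., t`
#' (so onsets require `t >= 6`).
#'
#' @param rate Hourly rate series (mL/kg/h).
#' @param window Sustained-low window length in hours (default 6).
#' @param threshold Rate threshold in mL/kg/h (default 0.5, strict `<`).
#' @return Integer 0/1 series, same length as `rate`.
#' @export
aki_onset <- function(rate, window = 6L, threshold = 0.5) {
  T_hours <- length(rate)
  below <- as.integer(rate < threshold)
  onset <- integer(T_hours)
  if (T_hours >= window) {
    run <- cumsum(below)
    full <- run - c(rep(0L, window), utils::head(run, T_hours - window))
    onset[window:T_hours] <- as.integer(full[window:T_hours] == window)
  }
  onset
}

#' 6-hour-ahead AKI classification label
#'
#' `y_t = 1` when the rate is strictly below the threshold for every hour
#' in `(t, t+6]`, i.e. the sustained-low window lies fully inside the next
#' 6 hours.  Under this reading the label for time `t` first becomes
#' observable at time `t+6`, which is what the lagged feedback mechanism
#' relies on.  `strict_window = FALSE` instead labels `y_t = 1` when ANY
#' onset hour (windows possibly straddling `t`) falls in `(t, t+6]`.
#'
#' @param rate Hourly rate series.
#' @param horizon Prediction horizon in hours (default 6).
#' @param threshold Rate threshold (default 0.5).
#' @param strict_window If `TRUE` (default) require the whole window
#'   inside the horizon; see Details.
#' @return Numeric series of length `length(rate)` with `y_t` for
#'   `t <= T - horizon` and `NA` beyond (undefined labels).
#' @export
next6_label <- function(rate, horizon = 6L, threshold = 0.5,
                        strict_window = TRUE) {
  T_hours <- length(rate)
  y <- rep(NA_real_, T_hours)
  if (T_hours < horizon + 1L) return(y)
  if (strict_window) {
    below <- as.integer(rate < threshold)
    run <- cumsum(below)
    # windows (t, t+horizon]: all hours below
    idx <- seq_len(T_hours - horizon)
    y[idx] <- as.numeric(run[idx + horizon] - run[idx] == horizon)
  } else {
    onset <- aki_onset(rate, window = horizon, threshold = threshold)
    idx <- seq_len(T_hours - horizon)
    cs <- cumsum(onset)
    y[idx] <- as.numeric(cs[idx + horizon] - cs[idx] > 0)
  }
  y
}

#' Next-6-hour urine output regression target
#'
#' @param urine Hourly urine output (mL/h), raw values.
#' @param horizon Horizon in hours (default 6).
#' @return Series with `Y_t = sum(u[(t+1):(t+horizon)])` for
#'   `t <= T - horizon`, `NA` beyond.
#' @export
next6_urine <- function(urine, horizon = 6L) {
  T_hours <- length(urine)
  y <- rep(NA_real_, T_hours)
  if (T_hours < horizon + 1L) return(y)
  cs <- cumsum(urine)
  idx <- seq_len(T_hours - horizon)
  y[idx] <- cs[idx + horizon] - cs[idx]
  y
}

#' Risk score and binary label from a predicted 6-hour urine output
#'
#' The regression variant predicts total urine over the next 6 hours; the
#' implied mean rate is compared with the 0.5 mL/kg/h criterion.
#'
#' @param Y_hat Predicted total urine over the horizon (mL).
#' @param weight Patient weight in kg (> 0).
#' @param horizon Horizon in hours (default 6).
#' @param threshold Rate threshold (default 0.5).
#' @return List with `rate` (implied mean rate mL/kg/h), `score`
#'   (`threshold - rate`, monotone in risk, used for AUC) and `label`
#'   (1 when the implied rate is strictly below the threshold).
#' @export
regression_label <- function(Y_hat, weight, horizon = 6L, threshold = 0.5) {
  if (!is.finite(weight) || weight <= 0) stopf("'weight' must be > 0")
  rate <- Y_hat / (horizon * weight)
  list(rate = rate, score = threshold - rate,
       label = as.numeric(rate < threshold))
}

#' Full label series for one stay
#'
#' Computes the per-hour rate, below-threshold flag, RIFLE onset flag, the
#' 6-hour-ahead classification label `y`, the regression target `Y`, and
#' the evaluation mask `valid_eval` (`t > horizon` with `y` defined) from
#' raw imputed hourly urine output.
#'
#' @param urine Hourly urine output (mL/h), raw values.
#' @param weight Patient weight (kg).
#' @param horizon Prediction horizon / RIFLE window (hours, default 6).
#' @param observed Optional 0/1 vector flagging directly observed (vs
#'   imputed) urine hours; recorded in the table as `urine_observed`.
#' @param strict_window Passed to [next6_label()].
#' @return data.frame with columns `hour`, `rate`, `below`, `onset`, `y`,
#'   `Y`, `valid_eval` (and `urine_observed` when `observed` is given).
#' @export
label_series <- function(urine, weight, horizon = 6L, observed = NULL,
                         strict_window = TRUE) {
  T_hours <- length(urine)
  rate <- urine_rate(urine, weight)
  y <- next6_label(rate, horizon = horizon, strict_window = strict_window)
  out <- data.frame(
    hour = seq_len(T_hours),
    rate = rate,
    below = as.integer(rate < 0.5),
    onset = aki_onset(rate, window = horizon),
    y = y,
    Y = next6_urine(urine, horizon = horizon),
    valid_eval = as.integer(seq_len(T_hours) > horizon & !is.na(y))
  )
  if (!is.null(observed)) out$urine_observed <- as.integer(observed)
  out
}

#' Write per-stay label tables as delimited text
#'
#' @param labels Named list of label data.frames (names = stay ids), as
#'   produced by [label_series()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_label_tables <- function(labels, path) {
  rows <- do.call(rbind, lapply(names(labels), function(id)
    cbind(stay_id = id, labels[[id]])))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
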