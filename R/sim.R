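#' Configuration for the synthetic ICU cohort simulator
#'
#' The simulator emulates the variable classes of a critical-care EHR
#' extract: hourly vitals, irregularly sampled labs, hourly urine output
#' driven by a latent renal state with occasional injury/recovery
#' episodes, 0/1 intervention flags, and static demographics with binary
#' comorbidity indicators.  It exists so that the whole modeling pipeline
#' is trainable and testable without access to credentialed ICU databases.
#'
#' The latent renal state \eqn{r_t \in [0,1]} (1 = healthy) relaxes toward
#' 1 with a configurable half-life and drops by a random depth in
#' \[0.4, 0.9\] at injury onsets, which occur independently each hour with
#' probability `injury_rate`.  Hourly urine output is
#' \eqn{u_t = \max(0,\; w\,(0.25 + 1.25\,r_t) + \epsilon)} mL/h for a
#' patient of weight \eqn{w} kg, so the urine rate crosses the
#' 0.5 mL/kg/h AKI threshold exactly when \eqn{r_t < 0.2} in the
#' noiseless limit.  Lab values track \eqn{1 - r} with a lag
#' (creatinine-like behaviour).
#'
#' @param n_stays Number of ICU stays to simulate.
#' @param min_hours,max_hours Stay length bounds in hours.  The default
#'   minimum of 13 guarantees at least one evaluable prediction step.
#' @param injury_rate Per-hour probability of an injury episode onset.
#' @param recovery_halflife Hours for the renal deficit \eqn{1-r} to halve.
#' @param noise_sd_vitals,noise_sd_labs,noise_sd_urine Noise standard
#'   deviations on the natural scales of the respective variables (the
#'   vitals/labs SDs are per-variable rescaled to physiological units).
#' @param lab_gap_range Range (hours) of the uniform gap between lab draws.
#' @param n_comorbidities Number of binary comorbidity flags.
#' @param seed Integer master seed; every stay gets an independent
#'   substream derived from `(seed, stay_index)`.
#' @return An object of class `aki_sim_config`.
#' @export
sim_config <- function(n_stays = 100L,
                       min_hours = 13L, max_hours = 96L,
                       injury_rate = 0.03,
                       recovery_halflife = 60,
                       noise_sd_vitals = 2.5,
                       noise_sd_labs = 0.25,
                       noise_sd_urine = 10,
                       lab_gap_range = c(4, 12),
                       n_comorbidities = 25L,
                       seed = 1L) {
  for (nm in c("n_stays", "min_hours", "max_hours", "injury_rate",
               "recovery_halflife", "noise_sd_vitals", "noise_sd_labs",
               "noise_sd_urine", "n_comorbidities", "seed"))
    assert_finite_scalar(get(nm), nm)
  if (!all(is.finite(lab_gap_range)) || length(lab_gap_range) != 2L)
    stopf("'lab_gap_range' must be two finite numbers")
  if (injury_rate < 0 || injury_rate > 1)
    stopf("'injury_rate' must lie in [0, 1]")
  if (min_hours < 1 || max_hours < min_hours)
    stopf("stay-length bounds must satisfy 1 <= min_hours <= max_hours")
  if (noise_sd_vitals < 0 || noise_sd_labs < 0 || noise_sd_urine < 0 ||
      recovery_halflife <= 0)
    stopf("noise SDs must be >= 0 and recovery_halflife > 0")
  structure(list(
    n_stays = as.integer(n_stays),
    min_hours = as.integer(min_hours), max_hours = as.integer(max_hours),
    injury_rate = injury_rate, recovery_halflife = recovery_halflife,
    noise_sd_vitals = noise_sd_vitals, noise_sd_labs = noise_sd_labs,
    noise_sd_urine = noise_sd_urine,
    lab_gap_range = sort(as.numeric(lab_gap_range)),
    n_comorbidities = as.integer(n_comorbidities),
    seed = as.integer(seed)
  ), class = "aki_sim_config")
}

# Latent recurrence shared by simulate_latent() and simulate_stay().
# Relaxation first, then a possible onset in the same hour.
latent_trajectory_impl <- function(config, T_hours) {
  decay <- 2^(-1 / config$recovery_halflife)
  onset <- stats::runif(T_hours) < config$injury_rate
  depth <- stats::runif(T_hours, 0.4, 0.9)
  r <- numeric(T_hours)
  r_prev <- 1
  for (t in seq_len(T_hours)) {
    rt <- 1 - (1 - r_prev) * decay
    if (onset[t]) rt <- max(0, rt - depth[t])
    r[t] <- rt
    r_prev <- rt
  }
  structure(list(renal_state = r, episode_onsets = which(onset)),
            class = "aki_latent")
}

#' Simulate the latent renal-state trajectory of one stay
#'
#' @param config An [sim_config()] object.
#' @param T_hours Stay length in hours (>= 1).
#' @param stay_index Stay index within the cohort; together with
#'   `config$seed` it fully determines the trajectory.
#' @return An `aki_latent` object with fields `renal_state` (per-hour
#'   \eqn{r_t \in [0,1]}) and `episode_onsets` (hour indices).
#' @export
simulate_latent <- function(config, T_hours, stay_index = 0L) {
  stopifnot(inherits(config, "aki_sim_config"))
  if (!is.finite(T_hours) || T_hours < 1) stopf("'T_hours' must be >= 1")
  withr::with_seed(
    substream_seed(config$seed, stay_index, 2L),
    latent_trajectory_impl(config, as.integer(T_hours))
  )
}

# Deterministic emission means given the latent state; exposed internally
# so that labeling behaviour can be reasoned about in closed form.
urine_mean <- function(r, weight) weight * (0.25 + 1.25 * r)

vital_means <- function(r) {
  d <- 1 - r
  list(heart_rate = 75 + 35 * d,
       mean_arterial_pressure = 85 - 20 * d,
       resp_rate = 15 + 8 * d,
       temperature = 36.8 + 0.8 * d)
}

lagged_state <- function(r, lag) r[pmax(1L, seq_along(r) - lag)]

lab_means <- function(r) {
  list(creatinine = 0.9 + 2.8 * (1 - lagged_state(r, 6L)),
       bun = 18 + 40 * (1 - lagged_state(r, 6L)),
       lactate = 1.2 + 2.5 * (1 - lagged_state(r, 2L)))
}

# Per-variable scale applied to the class-level noise SD so that one knob
# controls physiologically proportionate noise.
noise_scale <- c(heart_rate = 1, mean_arterial_pressure = 1,
                 resp_rate = 0.5, temperature = 0.05,
                 creatinine = 1, bun = 8, lactate = 1)

#' Simulate one ICU stay
#'
#' Draws stay length, statics, the latent trajectory and all event streams
#' from an independent substream determined by `(config$seed, stay_index)`,
#' so cohorts are reproducible under parallel generation and two stays
#' never share noise.
#'
#' @param config An [sim_config()] object.
#' @param stay_index Zero-based stay index (< `config$n_stays`).
#' @return An `aki_raw_stay`: list with `stay_id`, `static` (age, gender,
#'   weight, comorbidity flags), `events` (data.frame `time`, `variable`,
#'   `value`; times are fractional hours from admission), `length_hours`,
#'   and the `latent` trajectory (kept for diagnostics; not written to
#'   cohort files).
#' @export
simulate_stay <- function(config, stay_index) {
  stopifnot(inherits(config, "aki_sim_config"))
  if (stay_index < 0 || stay_index >= config$n_stays)
    stopf("stay_index %d outside [0, n_stays)", stay_index)

  meta <- withr::with_seed(substream_seed(config$seed, stay_index, 1L), {
    T_hours <- sample(seq(config$min_hours, config$max_hours), 1L)
    weight <- min(140, max(45, round(stats::rnorm(1, 80, 15))))
    list(T_hours = T_hours,
         age = sample(30:90, 1L),
         gender = stats::rbinom(1L, 1L, 0.5),
         weight = weight,
         comorbidities = stats::rbinom(config$n_comorbidities, 1L, 0.2))
  })
  T_hours <- meta$T_hours
  latent <- withr::with_seed(substream_seed(config$seed, stay_index, 2L),
                             latent_trajectory_impl(config, T_hours))
  r <- latent$renal_state

  events <- withr::with_seed(substream_seed(config$seed, stay_index, 3L), {
    th <- seq_len(T_hours) - 0.5   # hourly samples sit inside bin (t-1, t]
    ev <- list()
    u <- pmax(0, urine_mean(r, meta$weight) +
                   stats::rnorm(T_hours, 0, config$noise_sd_urine))
    ev[["urine_output"]] <- data.frame(time = th, variable = "urine_output",
                                       value = u)
    ev[["fluid_balance"]] <- data.frame(
      time = th, variable = "fluid_balance",
      value = cumsum(85 - u) / 24 +
        stats::rnorm(T_hours, 0, config$noise_sd_vitals))
    vm <- vital_means(r)
    for (nm in names(vm))
      ev[[nm]] <- data.frame(
        time = th, variable = nm,
        value = vm[[nm]] + stats::rnorm(T_hours, 0,
                                        config$noise_sd_vitals *
                                          noise_scale[[nm]]))
    # labs at irregular gaps; at least one draw per lab is guaranteed by
    # clamping the first draw inside the stay
    lm <- lab_means(r)
    for (nm in names(lm)) {
      gaps <- stats::runif(T_hours, config$lab_gap_range[1],
                           config$lab_gap_range[2])
      times <- cumsum(gaps)
      times <- times[times < T_hours]
      if (length(times) == 0L) times <- T_hours - 0.5
      hours <- pmax(1L, pmin(T_hours, ceiling(times)))
      ev[[nm]] <- data.frame(
        time = times, variable = nm,
        value = lm[[nm]][hours] +
          stats::rnorm(length(times), 0,
                       config$noise_sd_labs * noise_scale[[nm]]))
    }
    # interventions: 0/1 step functions
    vaso <- as.numeric(lagged_state(r, 1L) < 0.45)
    mv_start <- sample(seq_len(T_hours), 1L)
    mv_dur <- stats::rgeom(1L, 1 / 12) + 1L
    mv <- as.numeric(seq_len(T_hours) >= mv_start &
                       seq_len(T_hours) < mv_start + mv_dur)
    sed_start <- sample(seq_len(T_hours), 1L)
    sed_dur <- stats::rgeom(1L, 1 / 8) + 1L
    sed <- as.numeric(seq_len(T_hours) >= sed_start &
                        seq_len(T_hours) < sed_start + sed_dur)
    ev[["vasopressor"]] <- data.frame(time = th, variable = "vasopressor",
                                      value = vaso)
    ev[["mech_vent"]] <- data.frame(time = th, variable = "mech_vent",
                                    value = mv)
    ev[["sedative"]] <- data.frame(time = th, variable = "sedative",
                                   value = sed)
    out <- do.call(rbind, ev)
    rownames(out) <- NULL
    out[order(out$time, out$variable), , drop = FALSE]
  })
  rownames(events) <- NULL

  structure(list(
    stay_id = sprintf("stay_%05d", stay_index),
    static = list(age = meta$age, gender = meta$gender,
                  weight = meta$weight,
                  comorbidities = meta$comorbidities),
    events = events,
    length_hours = T_hours,
    latent = latent
  ), class = "aki_raw_stay")
}

#' Simulate a full cohort
#'
#' @param config An [sim_config()] object.
#' @return List of `aki_raw_stay` objects of length `config$n_stays`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "aki_sim_config"))
  lapply(seq_len(config$n_stays) - 1L,
         function(i) simulate_stay(config, i))
}

#' Write a cohort as the long-events / static file pair
#'
#' Events go to a delimited text file with columns
#' `stay_id,time,variable,value` (time in fractional hours from
#' admission); statics to `stay_id,age,gender,weight,comorbidity_<i>`.
#' The pair round-trips losslessly through [read_cohort()]; stay length is
#' recovered there as the ceiling of the last event time (the simulator
#' emits urine output through the final hour, so this is exact).
#'
#' @param stays List of `aki_raw_stay`.
#' @param events_path,static_path Output file paths.
#' @return Invisibly, the two paths.
#' @export
write_cohort <- function(stays, events_path, static_path) {
  n_com <- if (length(stays)) length(stays[[1]]$static$comorbidities) else 25L
  ev <- if (length(stays)) {
    do.call(rbind, lapply(stays, function(s)
      cbind(stay_id = s$stay_id, s$events)))
  } else {
    data.frame(stay_id = character(), time = numeric(),
               variable = character(), value = numeric())
  }
  st <- if (length(stays)) {
    do.call(rbind, lapply(stays, function(s) {
      row <- data.frame(stay_id = s$stay_id, age = s$static$age,
                        gender = s$static$gender, weight = s$static$weight)
      com <- as.data.frame(as.list(s$static$comorbidities))
      names(com) <- paste0("comorbidity_", seq_len(n_com))
      cbind(row, com)
    }))
  } else {
    st <- data.frame(stay_id = character(), age = numeric(),
                     gender = numeric(), weight = numeric())
    for (i in seq_len(n_com)) st[[paste0("comorbidity_", i)]] <- numeric()
    st
  }
  for (p in c(events_path, static_path)) {
    d <- dirname(p)
    if (!dir.exists(d)) stopf("output directory does not exist: %s", d)
  }
  tryCatch({
    utils::write.csv(ev, events_path, row.names = FALSE, quote = FALSE)
    utils::write.csv(st, static_path, row.names = FALSE, quote = FALSE)
  }, error = function(e)
    stopf("failed writing cohort files (%s, %s): %s",
          events_path, static_path, conditionMessage(e)))
  invisible(c(events = events_path, static = static_path))
}
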