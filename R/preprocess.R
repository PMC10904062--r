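#' Read a cohort from the events / static file pair
#'
#' Inverse of [write_cohort()].  Events are grouped per stay and sorted by
#' time; variable names outside the registry ([aki_variables()]) are
#' rejected; stays declared in the static table but carrying no events are
#' excluded with a warning (stays must have every variable recorded at
#' least once to enter the cohort).
#'
#' @param events_path,static_path Paths written by [write_cohort()].
#' @return List of `aki_raw_stay`.
#' @export
read_cohort <- function(events_path, static_path) {
  for (p in c(events_path, static_path))
    if (!file.exists(p)) stopf("cohort file not found: %s", p)
  ev <- utils::read.csv(events_path, stringsAsFactors = FALSE)
  st <- utils::read.csv(static_path, stringsAsFactors = FALSE)
  need_ev <- c("stay_id", "time", "variable", "value")
  if (!all(need_ev %in% names(ev)))
    stopf("events file %s lacks columns: %s", events_path,
          paste(setdiff(need_ev, names(ev)), collapse = ", "))
  need_st <- c("stay_id", "age", "gender", "weight")
  if (!all(need_st %in% names(st)))
    stopf("static file %s lacks columns: %s", static_path,
          paste(setdiff(need_st, names(st)), collapse = ", "))
  if (nrow(ev) && (!is.numeric(ev$time) || !is.numeric(ev$value)))
    stopf("events file %s: 'time' and 'value' must be numeric", events_path)
  vars <- aki_variables()$name
  unknown <- setdiff(unique(ev$variable), vars)
  if (length(unknown))
    stopf("unknown variable(s) in events file: %s",
          paste(unknown, collapse = ", "))
  orphans <- setdiff(unique(ev$stay_id), st$stay_id)
  if (length(orphans))
    stopf("stay(s) present in events but absent from static table: %s",
          paste(orphans, collapse = ", "))
  com_cols <- grep("^comorbidity_", names(st), value = TRUE)
  com_cols <- com_cols[order(as.integer(sub("^comorbidity_", "", com_cols)))]

  stays <- list()
  for (i in seq_len(nrow(st))) {
    id <- st$stay_id[i]
    e <- ev[ev$stay_id == id, c("time", "variable", "value"), drop = FALSE]
    if (!nrow(e)) {
      warning(sprintf("stay %s has no recorded events; excluded", id),
              call. = FALSE)
      next
    }
    e <- e[order(e$time, e$variable), , drop = FALSE]
    rownames(e) <- NULL
    stays[[length(stays) + 1L]] <- structure(list(
      stay_id = id,
      static = list(age = st$age[i], gender = st$gender[i],
                    weight = st$weight[i],
                    comorbidities = as.numeric(st[i, com_cols])),
      events = e,
      length_hours = as.integer(ceiling(max(e$time)))
    ), class = "aki_raw_stay")
  }
  stays
}

#' Resample one stay onto the hourly grid with imputation
#'
#' Hour `t` covers the half-open interval `(t-1, t]`.  For each variable:
#' hours containing observations get their mean (mask 1); interior gaps
#' are filled with the inverse-time-distance weighted average of the
#' nearest observed hour on each side (which coincides with linear
#' interpolation between them); hours before the first / after the last
#' observation carry that observation (mask 0 in all imputed cases).
#' Values remain on their natural scales; normalization is applied later
#' by [apply_stats()].
#'
#' @param stay An `aki_raw_stay` with at least one event per variable.
#' @return An `aki_hourly_stay`: list with `stay_id`, `x` (T x D feature
#'   matrix), `mask` (T x D observed indicator), `feature_names`,
#'   `weight`, `T_hours`, `normalized = FALSE`.
#' @export
to_hourly_grid <- function(stay) {
  stopifnot(inherits(stay, "aki_raw_stay"))
  vars <- aki_variables()$name
  T_hours <- stay$length_hours
  x <- matrix(NA_real_, T_hours, length(vars),
              dimnames = list(NULL, vars))
  mask <- matrix(0L, T_hours, length(vars), dimnames = list(NULL, vars))
  for (j in seq_along(vars)) {
    e <- stay$events[stay$events$variable == vars[j], , drop = FALSE]
    if (!nrow(e))
      stopf("stay %s has no events for variable '%s'",
            stay$stay_id, vars[j])
    bin <- pmax(1L, pmin(T_hours, ceiling(e$time)))
    agg <- tapply(e$value, bin, mean)
    obs_hours <- as.integer(names(agg))
    mask[obs_hours, j] <- 1L
    if (length(obs_hours) == 1L) {
      x[, j] <- agg[[1]]
    } else {
      x[, j] <- stats::approx(obs_hours, as.numeric(agg),
                              xout = seq_len(T_hours), rule = 2)$y
    }
  }
  structure(list(stay_id = stay$stay_id, x = x, mask = mask,
                 feature_names = vars, weight = stay$static$weight,
                 T_hours = T_hours, normalized = FALSE),
            class = "aki_hourly_stay")
}

#' Fit cohort clipping and normalization statistics
#'
#' Per feature, pools all directly observed (mask 1) entries across the
#' supplied stays, sets clip bounds at the empirical 1st/99th percentiles,
#' and records the min and max of the clipped pool.  Static covariates
#' (from `statics`) get the same treatment.  Only the designated fitting
#' split should be passed in: the stay ids are recorded as provenance so
#' leakage into evaluation folds can be asserted.
#'
#' @param stays List of (pre-normalization) `aki_hourly_stay`.
#' @param statics Optional static table (as read by [read_cohort()] /
#'   built by [build_cohort()]) restricted to the same stays.
#' @param probs Clip percentiles (default `c(0.01, 0.99)`).
#' @return An `aki_cohort_stats` object: per-feature `lower`, `upper`,
#'   `min`, `max`, `scaled` flags, a parallel `static` block, and
#'   `provenance` (fitted stay ids).
#' @export
fit_cohort_stats <- function(stays, statics = NULL,
                             probs = c(0.01, 0.99)) {
  if (!length(stays)) stopf("need at least one stay to fit cohort stats")
  reg <- aki_variables()
  D <- nrow(reg)
  lower <- upper <- mn <- mx <- numeric(D)
  for (j in seq_len(D)) {
    pool <- unlist(lapply(stays, function(s)
      s$x[s$mask[, j] == 1L, j]), use.names = FALSE)
    if (!length(pool))
      stopf("feature '%s' has no observed entries in the fitting cohort",
            reg$name[j])
    b <- stats::quantile(pool, probs, names = FALSE, type = 7)
    lower[j] <- b[1]; upper[j] <- b[2]
    clipped <- pmin(pmax(pool, b[1]), b[2])
    mn[j] <- min(clipped); mx[j] <- max(clipped)
  }
  names(lower) <- names(upper) <- names(mn) <- names(mx) <- reg$name

  static_stats <- NULL
  if (!is.null(statics)) {
    sf <- aki_static_fields(sum(grepl("^comorbidity_", names(statics))))
    s_lower <- s_upper <- s_mn <- s_mx <- numeric(nrow(sf))
    for (k in seq_len(nrow(sf))) {
      pool <- statics[[sf$name[k]]]
      b <- stats::quantile(pool, probs, names = FALSE, type = 7)
      s_lower[k] <- b[1]; s_upper[k] <- b[2]
      clipped <- pmin(pmax(pool, b[1]), b[2])
      s_mn[k] <- min(clipped); s_mx[k] <- max(clipped)
    }
    static_stats <- list(names = sf$name, scaled = sf$scaled,
                         lower = s_lower, upper = s_upper,
                         min = s_mn, max = s_mx)
  }
  structure(list(feature_names = reg$name, scaled = reg$scaled,
                 lower = lower, upper = upper, min = mn, max = mx,
                 static = static_stats,
                 provenance = vapply(stays, `[[`, "", "stay_id")),
            class = "aki_cohort_stats")
}

clip_scale <- function(v, lower, upper, mn, mx) {
  v <- pmin(pmax(v, lower), upper)
  if (mx > mn) (v - mn) / (mx - mn) else rep(0, length(v))
}

#' Apply cohort statistics to one stay
#'
#' Clips each scaled feature to its percentile bounds and min-max maps it
#' into \[0, 1\]; constant features map to 0; binary intervention flags
#' pass through unscaled.  The observed mask is never modified.
#'
#' @param stay A pre-normalization `aki_hourly_stay`.
#' @param stats An [fit_cohort_stats()] result with matching features.
#' @return The normalized `aki_hourly_stay` (`normalized = TRUE`).
#' @export
apply_stats <- function(stay, stats) {
  stopifnot(inherits(stay, "aki_hourly_stay"),
            inherits(stats, "aki_cohort_stats"))
  if (!identical(stay$feature_names, stats$feature_names))
    stopf("feature names of stay %s do not match the cohort stats",
          stay$stay_id)
  x <- stay$x
  for (j in seq_along(stats$feature_names)) {
    if (!stats$scaled[j]) next
    x[, j] <- clip_scale(x[, j], stats$lower[j], stats$upper[j],
                         stats$min[j], stats$max[j])
  }
  stay$x <- x
  stay$normalized <- TRUE
  stay
}

#' Assemble the model feature matrix for one stay
#'
#' Concatenates the normalized time-series features with the static
#' covariates used as model inputs (age, gender, comorbidity flags —
#' weight is reserved for the labeling rule), min-max scaled with the same
#' cohort-stats machinery and broadcast to every hour.  Column order is
#' canonical (registry order, then static order) regardless of the input
#' ordering, and is recorded in the column names.
#'
#' @param stay A normalized `aki_hourly_stay`.
#' @param static_row One-row data.frame (or named list) with the stay's
#'   static fields.
#' @param stats The [fit_cohort_stats()] result (needs its `static` block).
#' @return T x D' numeric matrix with canonical column names.
#' @export
assemble_features <- function(stay, static_row, stats) {
  stopifnot(inherits(stay, "aki_hourly_stay"))
  if (!isTRUE(stay$normalized))
    stopf("assemble_features() expects a normalized stay")
  if (is.null(stats$static))
    stopf("cohort stats carry no static block; pass 'statics' to fit_cohort_stats()")
  ss <- stats$static
  feat_names <- ss$names[!(ss$names == "weight")]
  vals <- numeric(length(feat_names))
  for (k in seq_along(feat_names)) {
    nm <- feat_names[k]
    i <- match(nm, ss$names)
    v <- as.numeric(static_row[[nm]])
    if (is.null(static_row[[nm]]) || !is.finite(v))
      stopf("static field '%s' missing for stay %s", nm, stay$stay_id)
    vals[k] <- if (ss$scaled[i])
      clip_scale(v, ss$lower[i], ss$upper[i], ss$min[i], ss$max[i])
    else v
  }
  x <- stay$x[, stats$feature_names, drop = FALSE]  # canonical ts order
  statmat <- matrix(rep(vals, each = stay$T_hours), nrow = stay$T_hours,
                    dimnames = list(NULL, feat_names))
  cbind(x, statmat)
}

#' Build an in-memory cohort bundle from raw stays
#'
#' Runs hourly-grid resampling and labeling once (both are independent of
#' normalization).  Normalization statistics are fitted per split later
#' (see [cross_validate()]) to keep evaluation folds out of the stats.
#'
#' @param stays List of `aki_raw_stay`.
#' @param horizon Prediction horizon / RIFLE window in hours (default 6).
#' @param strict_window Passed to [label_series()].
#' @return An `aki_cohort`: list with `hourly` (pre-normalization
#'   `aki_hourly_stay` list), `statics` (data.frame), `labels` (named list
#'   of label tables), `horizon`.
#' @export
build_cohort <- function(stays, horizon = 6L, strict_window = TRUE) {
  hourly <- lapply(stays, to_hourly_grid)
  n_com <- length(stays[[1]]$static$comorbidities)
  statics <- do.call(rbind, lapply(stays, function(s) {
    row <- data.frame(stay_id = s$stay_id, age = s$static$age,
                      gender = s$static$gender, weight = s$static$weight)
    com <- as.data.frame(as.list(s$static$comorbidities))
    names(com) <- paste0("comorbidity_", seq_len(n_com))
    cbind(row, com)
  }))
  labels <- lapply(hourly, function(h) {
    j <- match("urine_output", h$feature_names)
    label_series(h$x[, j], h$weight, horizon = horizon,
                 observed = h$mask[, j], strict_window = strict_window)
  })
  names(labels) <- vapply(hourly, `[[`, "", "stay_id")
  structure(list(hourly = hourly, statics = statics, labels = labels,
                 horizon = as.integer(horizon)),
            class = "aki_cohort")
}

#' Normalize and assemble features for a set of stays
#'
#' @param cohort An `aki_cohort` from [build_cohort()].
#' @param stats Cohort stats fitted on the designated fitting split.
#' @param ids Stay ids to prepare (default: all).
#' @return List (named by stay id) of prepared stays: `features`
#'   (T x D' matrix), `y`, `Ytilde` (regression target scaled by
#'   `1 / (horizon * weight)`, i.e. mean rate in mL/kg/h), `valid_eval`,
#'   `weight`, `T_hours`.
#' @export
prepare_stays <- function(cohort, stats, ids = NULL) {
  stopifnot(inherits(cohort, "aki_cohort"))
  all_ids <- vapply(cohort$hourly, `[[`, "", "stay_id")
  ids <- ids %||% all_ids
  idx <- match(ids, all_ids)
  if (anyNA(idx)) stopf("unknown stay id(s): %s",
                        paste(ids[is.na(idx)], collapse = ", "))
  out <- lapply(idx, function(i) {
    h <- apply_stats(cohort$hourly[[i]], stats)
    srow <- cohort$statics[cohort$statics$stay_id == h$stay_id, ,
                           drop = FALSE]
    lab <- cohort$labels[[h$stay_id]]
    list(stay_id = h$stay_id,
         features = assemble_features(h, srow, stats),
         y = lab$y,
         Ytilde = lab$Y / (cohort$horizon * h$weight),
         valid_eval = lab$valid_eval,
         weight = h$weight,
         T_hours = h$T_hours)
  })
  names(out) <- ids
  out
}
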