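#' Variable registry for the ICU feature set
#'
#' The package works with a fixed vocabulary of clinical variables grouped
#' into the classes found in critical-care EHR extracts: vital signs
#' (recorded hourly), lab measurements (sampled irregularly), fluids
#' (hourly urine output and fluid balance), and binary intervention flags.
#' Static covariates (demographics and comorbidity indicators) live in a
#' separate per-stay table.  Unknown variable names are rejected by the
#' cohort reader so that typos never silently become all-imputed columns.
#'
#' @param n_comorbidities Number of binary comorbidity flags in the static
#'   table (default 25).
#' @return For `aki_variables()`, a data.frame with columns `name`, `class`
#'   (`vital`, `lab`, `fluid`, `intervention`) and `scaled` (whether the
#'   variable takes part in min-max normalization; binary intervention
#'   flags pass through unscaled).  For `aki_static_fields()`, the same
#'   layout for the static table (`weight` is kept for labeling but is not
#'   a model feature).
#' @export
aki_variables <- function() {
  data.frame(
    name = c("heart_rate", "mean_arterial_pressure", "resp_rate",
             "temperature",
             "creatinine", "bun", "lactate",
             "urine_output", "fluid_balance",
             "mech_vent", "vasopressor", "sedative"),
    class = c(rep("vital", 4), rep("lab", 3), rep("fluid", 2),
              rep("intervention", 3)),
    scaled = c(rep(TRUE, 9), rep(FALSE, 3)),
    stringsAsFactors = FALSE
  )
}

#' @rdname aki_variables
#' @export
aki_static_fields <- function(n_comorbidities = 25) {
  data.frame(
    name = c("age", "gender", "weight",
             paste0("comorbidity_", seq_len(n_comorbidities))),
    scaled = c(TRUE, FALSE, TRUE, rep(FALSE, n_comorbidities)),
    feature = c(TRUE, TRUE, FALSE, rep(TRUE, n_comorbidities)),
    stringsAsFactors = FALSE
  )
}

#' Names of the static columns used as model features
#' @param n_comorbidities Number of comorbidity flags.
#' @return Character vector (age, gender, comorbidity flags).
#' @export
aki_static_feature_names <- function(n_comorbidities = 25) {
  sf <- aki_static_fields(n_comorbidities)
  sf$name[sf$feature]
}
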