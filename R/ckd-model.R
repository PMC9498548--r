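## Stage keys used throughout: "stage1".."stage5" and "esrd".
ckd_stages <- c("stage1", "stage2", "stage3", "stage4", "stage5", "esrd")

## Parameter fields by unit class. Percentage-rate fields are rounded to
## two decimal places at model build time; bias components are a
## dimensionless bias unit and are not rounded (published values such as
## 0.073 carry three decimals).
ckd_percentage_fields <- function() {
  c("diabetes_rate", "hypertension_rate", "diet_rate", "lifestyle_rate",
    paste0("base_progression_rate_", ckd_stages[1:5]),
    "dialysis_rate", "transplant_rate", "esrd_death_rate")
}

ckd_bias_fields <- function() {
  as.vector(outer(c("patient_bias_", "provider_bias_", "nephrologist_bias_",
                    "system_bias_"), ckd_stages, paste0))
}

ckd_fraction_fields <- function() c("monitored_slowdown", "screening_coverage")

ckd_param_fields <- function() {
  c("population_init", ckd_percentage_fields(), ckd_bias_fields(),
    ckd_fraction_fields(), "bias_gain")
}

#' CKD model parameters
#'
#' All named rates of the CKD disparity model. Defaults are the base-run
#' values: the Tennessee 2020 census population of 6,910,840 in the
#' population stock, diabetes and hypertension rates of 0.80 percentage
#' rate per year, and the per-stage primary-care-provider bias levels 0.8
#' (stage 1), 0.08 (stage 2), 0.16 (stage 3), 0.073 (stage 4), 0.152
#' (stage 5) and 0.33 (ESRD). Parameters with no published value (diet and
#' lifestyle rates, the remaining bias components, base progression rates,
#' ESRD outflow rates, the monitored-treatment slowdown, screening
#' coverage and the bias-to-unmonitored gain) carry documented synthetic
#' defaults chosen so the base run pushes nonzero flow through every stage
#' by 2022; see the package vignette.
#'
#' Units: `*_rate` and `base_progression_rate_*` are percentage rates per
#' year (a value p means p/100 of the stock per year) and are stored
#' rounded to two decimals when the model is built; `*_bias_*` are
#' dimensionless bias levels; `monitored_slowdown` and
#' `screening_coverage` are fractions in [0, 1]; `bias_gain` converts
#' total bias to an unmonitored-treatment fraction (1/bias).
#'
#' @param ... Named overrides of any field, e.g.
#'   `ckd_parameters(diabetes_rate = 1.15)`.
#' @return A named list of class `ckd_params`.
#' @seealso [build_ckd_model()], [total_bias()], [unmonitored_fraction()]
#' @export
#' @examples
#' p <- ckd_parameters()
#' p$population_init
#' total_bias("stage1", p)
ckd_parameters <- function(...) {
  p <- list(
    population_init = 6910840,
    diabetes_rate = 0.80, hypertension_rate = 0.80,
    diet_rate = 0.80, lifestyle_rate = 0.80,
    # provider bias: published base values per stage
    provider_bias_stage1 = 0.8, provider_bias_stage2 = 0.08,
    provider_bias_stage3 = 0.16, provider_bias_stage4 = 0.073,
    provider_bias_stage5 = 0.152, provider_bias_esrd = 0.33,
    # remaining bias components: synthetic defaults (see vignette)
    patient_bias_stage1 = 0.10, patient_bias_stage2 = 0.10,
    patient_bias_stage3 = 0.10, patient_bias_stage4 = 0.10,
    patient_bias_stage5 = 0.10, patient_bias_esrd = 0.10,
    nephrologist_bias_stage1 = 0.05, nephrologist_bias_stage2 = 0.05,
    nephrologist_bias_stage3 = 0.05, nephrologist_bias_stage4 = 0.05,
    nephrologist_bias_stage5 = 0.05, nephrologist_bias_esrd = 0.05,
    system_bias_stage1 = 0.10, system_bias_stage2 = 0.10,
    system_bias_stage3 = 0.10, system_bias_stage4 = 0.10,
    system_bias_stage5 = 0.10, system_bias_esrd = 0.10,
    # synthetic base progression rates, %/yr, fastest at the earliest stage
    base_progression_rate_stage1 = 8, base_progression_rate_stage2 = 6,
    base_progression_rate_stage3 = 4, base_progression_rate_stage4 = 3,
    base_progression_rate_stage5 = 2,
    monitored_slowdown = 0.25, screening_coverage = 0.30, bias_gain = 0.5,
    # ESRD outflows, %/yr
    dialysis_rate = 40, transplant_rate = 15, esrd_death_rate = 10
  )
  overrides <- list(...)
  if (length(overrides) == 1L && is.list(overrides[[1L]]) &&
      is.null(names(overrides))) {
    overrides <- overrides[[1L]]
  }
  if (length(overrides)) {
    unknown <- setdiff(names(overrides), names(p))
    if (length(unknown) || is.null(names(overrides)) ||
        any(!nzchar(names(overrides)))) {
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    p[names(overrides)] <- overrides
  }
  validate_ckd_parameters(p)
  structure(p, class = "ckd_params")
}

#' Base-run parameter set
#'
#' Convenience alias for [ckd_parameters()] with no overrides.
#' @return A `ckd_params` object holding the base-run values.
#' @export
default_parameters <- function() ckd_parameters()

validate_ckd_parameters <- function(p) {
  missing <- setdiff(ckd_param_fields(), names(p))
  if (length(missing)) {
    stop("missing parameter(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (f in ckd_param_fields()) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("parameter '", f, "' must be a single finite number", call. = FALSE)
    }
    if (v < 0) stop("parameter '", f, "' must be >= 0 (got ", v, ")",
                    call. = FALSE)
  }
  for (f in ckd_fraction_fields()) {
    if (p[[f]] > 1) stop("parameter '", f, "' must lie in [0, 1] (got ",
                         p[[f]], ")", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.ckd_params <- function(x, ...) {
  cat("CKD model parameters (", length(x), " fields)\n", sep = "")
  cat("  population_init:", format(x$population_init, big.mark = ","), "\n")
  cat("  risk rates (%/yr): diabetes", x$diabetes_rate,
      "| hypertension", x$hypertension_rate,
      "| diet", x$diet_rate, "| lifestyle", x$lifestyle_rate, "\n")
  tb <- vapply(ckd_stages, total_bias, numeric(1L), params = x)
  cat("  total bias by stage:", paste(ckd_stages, round(tb, 3), sep = "=",
                                      collapse = " "), "\n")
  invisible(x)
}

normalize_stage <- function(stage) {
  if (is.numeric(stage)) {
    stopifnot(stage %in% 1:5)
    return(paste0("stage", stage))
  }
  stage <- tolower(stage)
  if (!stage %in% ckd_stages) {
    stop("unknown stage '", stage, "' (expected stage1..stage5 or esrd)",
         call. = FALSE)
  }
  stage
}

#' Cumulative bias at a CKD stage
#'
#' The model treats the treatment-and-management bias at each stage as the
#' cumulative (additive) disparity contributed by the patients themselves
#' (non-adherence to self-care), the primary care providers, the
#' nephrologists and the healthcare system.
#'
#' @param stage `"stage1"`..`"stage5"`, `"esrd"`, or an integer 1-5.
#' @param params A [ckd_parameters()] object.
#' @return The total bias (dimensionless) at that stage.
#' @export
total_bias <- function(stage, params) {
  stage <- normalize_stage(stage)
  params[[paste0("patient_bias_", stage)]] +
    params[[paste0("provider_bias_", stage)]] +
    params[[paste0("nephrologist_bias_", stage)]] +
    params[[paste0("system_bias_", stage)]]
}

#' Unmonitored-treatment fraction implied by a bias level
#'
#' Converts a stage's total bias into the fraction of that stage's
#' patients whose CKD goes unmonitored:
#' `clamp(bias_gain * bias * (1 - screening_coverage), 0, 1)`.
#' Screening via eGFR and serum-albumin testing is summarised by the
#' single coverage fraction, which shrinks the unmonitored share; the
#' result is monotone non-decreasing in bias, and the monitored fraction
#' is its complement.
#'
#' @param bias Total bias (>= 0), e.g. from [total_bias()].
#' @param params A [ckd_parameters()] object (uses `bias_gain` and
#'   `screening_coverage`).
#' @return Fraction in [0, 1].
#' @export
unmonitored_fraction <- function(bias, params) {
  stopifnot(is.numeric(bias), all(bias >= 0))
  pmin(1, pmax(0, params$bias_gain * bias * (1 - params$screening_coverage)))
}

#' Build the CKD stage-ladder stock-flow model
#'
#' Constructs the full disparity model as a simulatable [sd_model()]:
#'
#' * Stocks: `Population` (initialised to `population_init`), `Stage1`..
#'   `Stage5`, `ESRD`, `Dialysis`, `Transplant`, `Deaths`, all starting at
#'   0, plus cumulative counters `ProgressionTo2`..`ProgressionTo5`,
#'   `ProgressionToESRD` and `DeathIncidence` fed by the corresponding
#'   flows.
#' * Incidence: `Population -> Stage1` at
#'   `Population * mean(risk rates) / 100`, the four risk factors being
#'   diabetes, hypertension, dietary and lifestyle patterns.
#' * Progression `k -> k+1` (stage 5 progresses to ESRD):
#'   `Stage_k * (base_progression_rate_k / 100) * (u_k + rho * (1 - u_k))`
#'   where `u_k` is the stage's [unmonitored_fraction()] of its
#'   [total_bias()] and `rho = monitored_slowdown` is the relative
#'   progression speed under monitored care.
#' * ESRD outflows to `Dialysis` and `Transplant` at their percentage
#'   rates; the `ESRD -> Deaths` flow is modulated by the ESRD-stage
#'   monitored/unmonitored factor, so raising ESRD bias raises death
#'   incidence.
#'
#' Percentage-rate parameters are rounded to two decimal places at build
#' time; bias components are not.
#'
#' @param params A [ckd_parameters()] object.
#' @return A validated [sd_model()].
#' @export
#' @examples
#' m <- build_ckd_model(ckd_parameters())
#' traj <- simulate(m, config = sim_config(2010, 2022))
#' endpoint(traj, "ProgressionTo2", 2022)
build_ckd_model <- function(params) {
  if (!inherits(params, "ckd_params")) params <- ckd_parameters(params)
  validate_ckd_parameters(params)
  pv <- unclass(params)
  for (f in ckd_percentage_fields()) pv[[f]] <- round(pv[[f]], 2)

  stage_stock <- c(stage1 = "Stage1", stage2 = "Stage2", stage3 = "Stage3",
                   stage4 = "Stage4", stage5 = "Stage5", esrd = "ESRD")
  counter_of <- c(stage1 = "ProgressionTo2", stage2 = "ProgressionTo3",
                  stage3 = "ProgressionTo4", stage4 = "ProgressionTo5",
                  stage5 = "ProgressionToESRD")

  stocks <- c(
    list(sd_stock("Population", pv$population_init)),
    lapply(unname(stage_stock), sd_stock),
    lapply(c("Dialysis", "Transplant", "Deaths"), sd_stock),
    lapply(c(unname(counter_of), "DeathIncidence"), sd_stock)
  )

  aux <- list(
    sd_aux("incidence_rate",
           paste0("Population * ((diabetes_rate + hypertension_rate + ",
                  "diet_rate + lifestyle_rate) / 4) / 100"),
           "persons/year")
  )
  for (s in ckd_stages) {
    aux <- c(aux, list(
      sd_aux(paste0("bias_", s),
             paste0("patient_bias_", s, " + provider_bias_", s,
                    " + nephrologist_bias_", s, " + system_bias_", s),
             "bias"),
      sd_aux(paste0("unmonitored_", s),
             paste0("min(1, max(0, bias_gain * bias_", s,
                    " * (1 - screening_coverage)))"),
             "fraction")
    ))
  }
  for (k in 1:5) {
    s <- ckd_stages[k]
    aux <- c(aux, list(sd_aux(
      paste0("progression_rate_", s),
      paste0(stage_stock[[s]], " * (base_progression_rate_", s, " / 100) * ",
             "(unmonitored_", s, " + monitored_slowdown * (1 - unmonitored_",
             s, "))"),
      "persons/year")))
  }
  aux <- c(aux, list(
    sd_aux("dialysis_outflow", "ESRD * dialysis_rate / 100", "persons/year"),
    sd_aux("transplant_outflow", "ESRD * transplant_rate / 100", "persons/year"),
    sd_aux("esrd_death_outflow",
           paste0("ESRD * (esrd_death_rate / 100) * (unmonitored_esrd + ",
                  "monitored_slowdown * (1 - unmonitored_esrd))"),
           "persons/year")
  ))

  flows <- list(sd_flow("incidence", "Population", "Stage1", "incidence_rate"))
  for (k in 1:5) {
    s <- ckd_stages[k]
    dest <- if (k < 5) stage_stock[[ckd_stages[k + 1L]]] else "ESRD"
    flows <- c(flows,
               list(sd_flow(paste0("progression_", s), stage_stock[[s]], dest,
                            paste0("progression_rate_", s)),
                    sd_flow(paste0("count_", tolower(counter_of[[s]])),
                            BOUNDARY, counter_of[[s]],
                            paste0("progression_rate_", s))))
  }
  flows <- c(flows, list(
    sd_flow("to_dialysis", "ESRD", "Dialysis", "dialysis_outflow"),
    sd_flow("to_transplant", "ESRD", "Transplant", "transplant_outflow"),
    sd_flow("esrd_deaths", "ESRD", "Deaths", "esrd_death_outflow"),
    sd_flow("count_death_incidence", BOUNDARY, "DeathIncidence",
            "esrd_death_outflow")
  ))

  spec <- sd_model(stocks = stocks, flows = flows, auxiliaries = aux,
                   parameters = pv[ckd_param_fields()],
                   name = "ckd-disparity")
  rep <- validate_sd_model(spec)
  if (nrow(rep) > 0L) {
    stop("internal error: CKD model fails validation:\n  ",
         paste(rep$message, collapse = "\n  "), call. = FALSE)
  }
  spec
}

## State stocks (persons actually somewhere in the system) as opposed to
## cumulative counters; the sum over these is conserved at population_init.
ckd_state_stocks <- function() {
  c("Population", "Stage1", "Stage2", "Stage3", "Stage4", "Stage5", "ESRD",
    "Dialysis", "Transplant", "Deaths")
}

ckd_counter_stocks <- function() {
  c("ProgressionTo2", "ProgressionTo3", "ProgressionTo4", "ProgressionTo5",
    "ProgressionToESRD", "DeathIncidence")
}

#' Reported ESRD burden counts for Tennessee, 2021
#'
#' The American Kidney Fund counts used as the model's worked example:
#' 11,495 people on dialysis, 4,167 with a kidney transplant, and the
#' total ESRD burden of 15,662 they sum to.
#'
#' @return Named numeric vector with elements `dialysis`, `transplant`
#'   and `total`.
#' @export
#' @examples
#' cts <- tennessee_esrd_counts()
#' cts[["dialysis"]] + cts[["transplant"]] == cts[["total"]]
tennessee_esrd_counts <- function() {
  c(dialysis = 11495, transplant = 4167, total = 15662)
}
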