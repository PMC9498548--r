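#' Define a scenario
#'
#' A scenario is a named set of parameter overrides applied as whole-run
#' constants against a base parameter set ("base" vs "current" runs).
#'
#' @param name Scenario name.
#' @param overrides Named list/vector of [ckd_parameters()] field
#'   overrides (may be empty).
#' @return An object of class `ckd_scenario`.
#' @export
scenario <- function(name, overrides = list()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  overrides <- as.list(overrides)
  if (length(overrides) && (is.null(names(overrides)) ||
                            any(!nzchar(names(overrides))))) {
    stop("scenario overrides must be named", call. = FALSE)
  }
  unknown <- setdiff(names(overrides), ckd_param_fields())
  if (length(unknown)) {
    stop("scenario '", name, "': unknown parameter(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  structure(list(name = name, overrides = overrides), class = "ckd_scenario")
}

#' @export
print.ckd_scenario <- function(x, ...) {
  cat("Scenario '", x$name, "'", sep = "")
  if (length(x$overrides)) {
    cat(": ", paste(names(x$overrides), unlist(x$overrides), sep = " = ",
                    collapse = ", "), sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Packaged altered-rate scenarios
#'
#' The study's base-versus-current experiments as named scenarios:
#'
#' * `current` — diabetes rate 0.80 to 1.15 and hypertension rate 0.80 to
#'   1.25 (percentage rate);
#' * `stage1-bias` .. `stage5-bias`, `esrd-bias` — the per-stage
#'   primary-care-provider bias step changes 0.8 to 1.3, 0.08 to 1.55,
#'   0.16 to 1.32, 0.073 to 1.151, 0.152 to 0.275 and 0.33 to 0.72.
#'
#' @return Named list of [scenario()] objects.
#' @export
#' @examples
#' ckd_scenarios()[["current"]]
ckd_scenarios <- function() {
  specs <- list(
    scenario("current", list(diabetes_rate = 1.15, hypertension_rate = 1.25)),
    scenario("stage1-bias", list(provider_bias_stage1 = 1.3)),
    scenario("stage2-bias", list(provider_bias_stage2 = 1.55)),
    scenario("stage3-bias", list(provider_bias_stage3 = 1.32)),
    scenario("stage4-bias", list(provider_bias_stage4 = 1.151)),
    scenario("stage5-bias", list(provider_bias_stage5 = 0.275)),
    scenario("esrd-bias", list(provider_bias_esrd = 0.72))
  )
  names(specs) <- vapply(specs, `[[`, "", "name")
  specs
}

## downstream cumulative counter each bias scenario is expected to raise
scenario_downstream_series <- function() {
  c("stage1-bias" = "ProgressionTo2", "stage2-bias" = "ProgressionTo3",
    "stage3-bias" = "ProgressionTo4", "stage4-bias" = "ProgressionTo5",
    "stage5-bias" = "ProgressionToESRD", "esrd-bias" = "DeathIncidence")
}

#' Run a base/scenario trajectory pair
#'
#' Simulates the CKD model twice on an identical time grid: once with the
#' base parameters and once with the scenario overrides applied for the
#' whole run. The input parameter set is never modified.
#'
#' @param params Base [ckd_parameters()].
#' @param scen A [scenario()] (or a name from [ckd_scenarios()]).
#' @param config A [sim_config()].
#' @return An object of class `ckd_run_pair` with elements `base` and
#'   `scenario` (trajectories), `params`, `scenario_params` and `config`.
#' @export
run_pair <- function(params, scen, config = sim_config()) {
  if (is.character(scen)) {
    all <- ckd_scenarios()
    if (!scen %in% names(all)) stop("unknown scenario '", scen, "'",
                                    call. = FALSE)
    scen <- all[[scen]]
  }
  stopifnot(inherits(scen, "ckd_scenario"))
  if (!inherits(params, "ckd_params")) params <- ckd_parameters(params)
  scen_params <- unclass(params)
  scen_params[names(scen$overrides)] <- scen$overrides
  scen_params <- ckd_parameters(scen_params)
  base_traj <- simulate(build_ckd_model(params), config = config)
  scen_traj <- simulate(build_ckd_model(scen_params), config = config)
  structure(list(base = base_traj, scenario = scen_traj,
                 name = scen$name, params = params,
                 scenario_params = scen_params, config = config),
            class = "ckd_run_pair")
}

#' @export
print.ckd_run_pair <- function(x, ...) {
  cat("Base vs '", x$name, "' run pair, ", x$config$t_start, "-",
      x$config$t_end, "\n", sep = "")
  yr <- x$config$t_end
  for (s in c("ProgressionTo2", "ProgressionToESRD", "DeathIncidence")) {
    cat(sprintf("  %-18s base %12.1f   scenario %12.1f\n", s,
                endpoint(x$base, s, yr), endpoint(x$scenario, s, yr)))
  }
  invisible(x)
}

#' Overlay plot of one series for a base/scenario pair
#'
#' @param x A `ckd_run_pair`.
#' @param series Series name to plot (default `"ProgressionTo2"`).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.ckd_run_pair <- function(x, series = "ProgressionTo2", ...) {
  b <- get_series(x$base, series)
  s <- get_series(x$scenario, series)
  graphics::plot(x$base$times, b, type = "l", col = "black",
                 xlab = "year", ylab = series,
                 ylim = range(b, s), ...)
  graphics::lines(x$scenario$times, s, col = "red")
  graphics::legend("topleft", legend = c("base", x$name),
                   col = c("black", "red"), lty = 1, bty = "n")
  invisible(x)
}

#' Check pointwise dominance of a scenario over its base run
#'
#' Tests whether the scenario series is at least the base series at every
#' grid point (the qualitative comparison the study's figures make).
#'
#' @param pair A [run_pair()] result.
#' @param series Series name present in both trajectories.
#' @param tol Absolute slack for floating-point comparison.
#' @return List with `ok` (logical) and, when `ok` is `FALSE`,
#'   `first_violation` (the first time at which scenario < base).
#' @export
dominance_check <- function(pair, series, tol = 1e-9) {
  stopifnot(inherits(pair, "ckd_run_pair"))
  b <- get_series(pair$base, series)
  s <- get_series(pair$scenario, series)
  viol <- which(s < b - tol * pmax(abs(b), 1))
  if (length(viol) == 0L) {
    list(ok = TRUE, first_violation = NULL)
  } else {
    list(ok = FALSE, first_violation = pair$base$times[viol[1L]])
  }
}

#' Sweep one parameter and record an endpoint
#'
#' Runs one simulation per value of a single parameter and tabulates the
#' endpoint of a series at a given year.
#'
#' @param params Base [ckd_parameters()].
#' @param param Parameter field name to vary.
#' @param values Numeric vector of values (each must satisfy the field's
#'   invariants).
#' @param config A [sim_config()].
#' @param series Series name.
#' @param year Year on the grid (default `config$t_end`).
#' @return Data frame with columns `value` and `endpoint`.
#' @export
sweep_endpoint <- function(params, param, values, config = sim_config(),
                           series, year = config$t_end) {
  if (!inherits(params, "ckd_params")) params <- ckd_parameters(params)
  stopifnot(param %in% ckd_param_fields(), is.numeric(values),
            length(values) >= 1L)
  ep <- vapply(values, function(v) {
    p <- unclass(params)
    p[[param]] <- v
    traj <- simulate(build_ckd_model(ckd_parameters(p)), config = config)
    endpoint(traj, series, year)
  }, numeric(1L))
  data.frame(value = values, endpoint = ep)
}

#' Calibrate one parameter to hit a target endpoint
#'
#' Bisection on a single scalar parameter whose endpoint is monotone over
#' the bounds (direction established by evaluating both bounds). Stops
#' when the bracketing interval is narrower than `xtol`, and checks the
#' achieved endpoint against `tol`.
#'
#' @param params Base [ckd_parameters()].
#' @param param Parameter field name to fit.
#' @param target Target endpoint value.
#' @param series Series name.
#' @param year Year on the grid.
#' @param bounds Length-2 numeric search interval.
#' @param config A [sim_config()].
#' @param tol Endpoint tolerance (default `1e-6 * max(1, |target|)`).
#' @param xtol Parameter-interval tolerance (default 1e-6).
#' @return The fitted parameter value, with attributes `endpoint` and
#'   `iterations`. Errors with the achievable endpoint interval if the
#'   target lies outside it.
#' @export
#' @examples
#' \donttest{
#' p <- ckd_parameters()
#' cfg <- sim_config(2010, 2022, dt = 1 / 16)
#' truth <- simulate(build_ckd_model(ckd_parameters(diabetes_rate = 1.1)),
#'                   config = cfg)
#' calibrate_endpoint(p, "diabetes_rate",
#'                    target = endpoint(truth, "ProgressionTo2", 2022),
#'                    series = "ProgressionTo2", year = 2022,
#'                    bounds = c(0.2, 2), config = cfg)
#' }
calibrate_endpoint <- function(params, param, target, series, year, bounds,
                               config = sim_config(),
                               tol = 1e-6 * max(1, abs(target)),
                               xtol = 1e-6) {
  if (!inherits(params, "ckd_params")) params <- ckd_parameters(params)
  stopifnot(param %in% ckd_param_fields(), is.numeric(bounds),
            length(bounds) == 2L, bounds[1L] < bounds[2L])
  eval_at <- function(v) {
    p <- unclass(params)
    p[[param]] <- v
    traj <- simulate(build_ckd_model(ckd_parameters(p)), config = config)
    endpoint(traj, series, year)
  }
  lo <- bounds[1L]; hi <- bounds[2L]
  f_lo <- eval_at(lo); f_hi <- eval_at(hi)
  if (abs(target - f_lo) <= tol) {
    return(structure(lo, endpoint = f_lo, iterations = 0L))
  }
  if (abs(target - f_hi) <= tol) {
    return(structure(hi, endpoint = f_hi, iterations = 0L))
  }
  achievable <- sort(c(f_lo, f_hi))
  if (target < achievable[1L] || target > achievable[2L]) {
    stop("target ", target, " is outside the achievable endpoint interval [",
         format(achievable[1L]), ", ", format(achievable[2L]), "] for '",
         param, "' over [", lo, ", ", hi, "]", call. = FALSE)
  }
  increasing <- f_hi >= f_lo
  it <- 0L
  mid <- (lo + hi) / 2
  f_mid <- NA_real_
  while (hi - lo > xtol && it < 200L) {
    mid <- (lo + hi) / 2
    f_mid <- eval_at(mid)
    it <- it + 1L
    if ((f_mid < target) == increasing) lo <- mid else hi <- mid
  }
  mid <- (lo + hi) / 2
  f_mid <- eval_at(mid)
  if (abs(f_mid - target) > max(tol, abs(f_hi - f_lo) * xtol /
                                (bounds[2L] - bounds[1L]) * 4)) {
    warning("calibrated endpoint ", format(f_mid),
            " misses the target by ", format(abs(f_mid - target)))
  }
  structure(mid, endpoint = f_mid, iterations = it)
}
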