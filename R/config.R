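## YAML configuration: three top-level sections.
##
##   parameters:  one key per ckd_parameters() field (all optional;
##                missing fields take the base-run defaults)
##   simulation:  t_start, t_end, dt
##   scenarios:   list of {name, overrides: {field: value}}
##
## Unknown keys anywhere are rejected, with the offending key path named.

#' Read a model/scenario configuration file
#'
#' Parses a YAML configuration into a parameter set, a simulation
#' configuration and a (possibly empty) scenario list, enforcing every
#' field invariant. Unknown keys are rejected with their key path.
#'
#' @param path Path to a YAML file.
#' @return List with elements `parameters` ([ckd_parameters()]), `config`
#'   ([sim_config()]) and `scenarios` (named list of [scenario()]).
#' @seealso [write_ckd_config()]; a complete example ships at
#'   `system.file("extdata", "ckd-default.yaml", package = "ckdflow")`.
#' @export
read_ckd_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("config must be a YAML mapping", call. = FALSE)
  unknown <- setdiff(names(raw), c("parameters", "simulation", "scenarios"))
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  pars <- raw$parameters
  if (!is.null(pars)) {
    bad <- setdiff(names(pars), ckd_param_fields())
    if (length(bad)) {
      stop("unknown config key(s): ",
           paste0("parameters$", bad, collapse = ", "), call. = FALSE)
    }
  }
  params <- tryCatch(do.call(ckd_parameters, as.list(pars)),
                     error = function(e) {
                       stop("config 'parameters': ", conditionMessage(e),
                            call. = FALSE)
                     })
  sim <- raw$simulation
  if (!is.null(sim)) {
    bad <- setdiff(names(sim), c("t_start", "t_end", "dt"))
    if (length(bad)) {
      stop("unknown config key(s): ",
           paste0("simulation$", bad, collapse = ", "), call. = FALSE)
    }
  }
  config <- tryCatch(do.call(sim_config, as.list(sim)),
                     error = function(e) {
                       stop("config 'simulation': ", conditionMessage(e),
                            call. = FALSE)
                     })
  scen_raw <- raw$scenarios
  scenarios <- list()
  if (!is.null(scen_raw)) {
    if (!is.list(scen_raw)) stop("config 'scenarios' must be a list",
                                 call. = FALSE)
    for (i in seq_along(scen_raw)) {
      s <- scen_raw[[i]]
      bad <- setdiff(names(s), c("name", "overrides"))
      if (length(bad)) {
        stop("unknown config key(s): ",
             paste0("scenarios[[", i, "]]$", bad, collapse = ", "),
             call. = FALSE)
      }
      if (is.null(s$name)) {
        stop("scenarios[[", i, "]] is missing 'name'", call. = FALSE)
      }
      scenarios[[s$name]] <- scenario(s$name, as.list(s$overrides))
    }
  }
  list(parameters = params, config = config, scenarios = scenarios)
}

#' Write a model/scenario configuration file
#'
#' Inverse of [read_ckd_config()]: parameter sets round-trip exactly
#' (values are written with 15 significant digits).
#'
#' @param params A [ckd_parameters()] object.
#' @param config A [sim_config()].
#' @param scenarios Named list of [scenario()] objects (may be empty).
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_ckd_config <- function(params, config = sim_config(),
                             scenarios = list(), path) {
  if (!inherits(params, "ckd_params")) params <- ckd_parameters(params)
  doc <- list(
    parameters = unclass(params)[ckd_param_fields()],
    simulation = list(t_start = config$t_start, t_end = config$t_end,
                      dt = config$dt)
  )
  if (length(scenarios)) {
    doc$scenarios <- lapply(unname(scenarios), function(s) {
      list(name = s$name, overrides = s$overrides)
    })
  }
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}
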