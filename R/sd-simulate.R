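#' Simulation configuration
#'
#' Fixed-step explicit Euler over a calendar-year grid. The step count
#' `(t_end - t_start) / dt` must be a whole number.
#'
#' @param t_start Start year (e.g. 2010).
#' @param t_end End year (e.g. 2022); must exceed `t_start`.
#' @param dt Step size in years (default 0.0625, i.e. 1/16 year).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(t_start = 2010, t_end = 2022, dt = 0.0625) {
  stopifnot(is.numeric(t_start), is.numeric(t_end), is.numeric(dt))
  if (!(t_end > t_start)) stop("t_end must exceed t_start", call. = FALSE)
  if (!(dt > 0)) stop("dt must be positive", call. = FALSE)
  n <- (t_end - t_start) / dt
  if (abs(n - round(n)) > 1e-9) {
    stop("(t_end - t_start) / dt must be a whole number of steps", call. = FALSE)
  }
  structure(list(t_start = t_start, t_end = t_end, dt = dt,
                 n_steps = as.integer(round(n)), method = "euler"),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation: ", x$t_start, " to ", x$t_end, ", dt = ", x$dt,
      " (", x$n_steps, " Euler steps)\n", sep = "")
  invisible(x)
}

## Evaluation environment shared across steps: parameters bound once,
## stocks and t rebound per step, auxiliaries assigned in topological order.
make_eval_env <- function(spec) {
  e <- new.env(parent = baseenv())
  for (p in names(spec$parameters)) assign(p, spec$parameters[[p]], envir = e)
  e
}

eval_auxiliaries <- function(spec, env, order, parsed) {
  vals <- numeric(length(order))
  names(vals) <- order
  for (i in seq_along(order)) {
    v <- eval(parsed[[order[[i]]]], envir = env)
    if (!is.numeric(v) || length(v) != 1L) {
      stop("auxiliary '", order[[i]], "' did not evaluate to a single number",
           call. = FALSE)
    }
    assign(order[[i]], v, envir = env)
    vals[[i]] <- v
  }
  vals
}

## One Euler step. Nominal flow rates are read from their auxiliaries; a
## stock whose total outflow demand over the step exceeds its content has
## all its outflows scaled down proportionally so it lands exactly on 0.
## Returns the new state and the realized (post-limiting) flow rates.
step_state <- function(state, dt, nominal, src_idx, snk_idx, flow_names_) {
  bad <- !is.finite(nominal)
  if (any(bad)) {
    stop("non-finite flow value for flow '", flow_names_[which(bad)[1L]], "'",
         call. = FALSE)
  }
  out_tot <- numeric(length(state))
  for (j in seq_along(nominal)) {
    if (src_idx[j] > 0L) out_tot[src_idx[j]] <- out_tot[src_idx[j]] + nominal[j]
  }
  limit <- rep(1, length(state))
  pos <- out_tot > 0 & dt * out_tot > state
  limit[pos] <- state[pos] / (dt * out_tot[pos])
  realized <- nominal
  for (j in seq_along(nominal)) {
    if (src_idx[j] > 0L) realized[j] <- nominal[j] * limit[src_idx[j]]
  }
  new_state <- state
  for (j in seq_along(realized)) {
    if (src_idx[j] > 0L) new_state[src_idx[j]] <- new_state[src_idx[j]] - dt * realized[j]
    if (snk_idx[j] > 0L) new_state[snk_idx[j]] <- new_state[snk_idx[j]] + dt * realized[j]
  }
  # guard against floating-point undershoot when a stock is driven to its floor
  new_state[new_state < 0] <- 0
  list(state = new_state, realized = realized)
}

#' Advance a model state by one Euler step
#'
#' Applies the stock update `S(t + dt) = S(t) + dt * (inflows - outflows)`.
#' If a stock's outflow demand over the step exceeds its content, all its
#' outflows are scaled proportionally so the stock lands on 0 rather than
#' going negative.
#'
#' @param spec An [sd_model()].
#' @param state Named numeric vector of stock values (all stocks).
#' @param t Current time (years).
#' @param dt Step size (years).
#' @param parameters Optional named overrides of `spec$parameters`.
#' @return List with `state` (named stock vector at `t + dt`), `flows`
#'   (named realized flow rates used for the step) and `auxiliaries`
#'   (named auxiliary values at `t`).
#' @export
sd_step <- function(spec, state, t, dt, parameters = NULL) {
  stopifnot(inherits(spec, "sd_model"))
  spec <- apply_parameter_overrides(spec, parameters)
  sn <- stock_names(spec)
  stopifnot(all(sn %in% names(state)))
  state <- state[sn]
  ord <- order_auxiliaries(spec)
  parsed <- lapply(spec$auxiliaries, `[[`, "parsed")
  names(parsed) <- aux_names(spec)
  env <- make_eval_env(spec)
  assign("t", t, envir = env)
  for (i in seq_along(sn)) assign(sn[i], state[[i]], envir = env)
  auxv <- eval_auxiliaries(spec, env, ord, parsed)
  fn <- flow_names(spec)
  nominal <- vapply(spec$flows, function(f) auxv[[f$rate]], numeric(1L))
  src_idx <- match(vapply(spec$flows, `[[`, "", "source"), sn, nomatch = 0L)
  snk_idx <- match(vapply(spec$flows, `[[`, "", "sink"), sn, nomatch = 0L)
  res <- step_state(as.numeric(state), dt, nominal, src_idx, snk_idx, fn)
  names(res$state) <- sn
  names(res$realized) <- fn
  list(state = res$state, flows = res$realized, auxiliaries = auxv)
}

apply_parameter_overrides <- function(spec, parameters) {
  if (is.null(parameters)) return(spec)
  parameters <- unlist(parameters)
  unknown <- setdiff(names(parameters), names(spec$parameters))
  if (length(unknown)) {
    stop("unknown parameter override(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  spec$parameters[names(parameters)] <- parameters
  spec
}

#' Simulate a stock-and-flow model
#'
#' Runs fixed-step explicit Euler integration over the configured grid and
#' records every stock, realized flow and auxiliary at every grid point.
#' The run is fully deterministic: identical inputs give bitwise-identical
#' trajectories (`nsim`/`seed` are accepted for generic compatibility and
#' ignored beyond seeding).
#'
#' @param object An [sd_model()]; must pass [validate_sd_model()].
#' @param nsim Ignored (the engine is deterministic).
#' @param seed Ignored by the engine; accepted for [stats::simulate()]
#'   compatibility.
#' @param config A [sim_config()].
#' @param parameters Optional named parameter overrides, applied for the
#'   whole run.
#' @param ... Unused.
#' @return An `sd_trajectory`: list with `times` and matrices `stocks`,
#'   `flows`, `auxiliaries` (rows = grid points), plus units and the model.
#'   Flow and auxiliary rows hold the values evaluated at that grid time;
#'   the flows in row i are exactly those that advanced the state from
#'   time i to time i+1.
#' @seealso [endpoint()], [mass_balance()], [write_trajectory_csv()]
#' @export
simulate.sd_model <- function(object, nsim = 1, seed = NULL,
                              config = sim_config(), parameters = NULL, ...) {
  stopifnot(inherits(config, "sim_config"))
  spec <- apply_parameter_overrides(object, parameters)
  rep <- validate_sd_model(spec)
  if (nrow(rep) > 0L) {
    stop("model fails validation:\n  ", paste(rep$message, collapse = "\n  "),
         call. = FALSE)
  }
  sn <- stock_names(spec)
  fn <- flow_names(spec)
  ord <- order_auxiliaries(spec)
  parsed <- lapply(spec$auxiliaries, `[[`, "parsed")
  names(parsed) <- aux_names(spec)

  n <- config$n_steps
  times <- config$t_start + config$dt * (0:n)
  stocks <- matrix(NA_real_, n + 1L, length(sn), dimnames = list(NULL, sn))
  flows <- matrix(NA_real_, n + 1L, length(fn), dimnames = list(NULL, fn))
  auxs <- matrix(NA_real_, n + 1L, length(ord), dimnames = list(NULL, ord))

  state <- vapply(spec$stocks, `[[`, 0, "initial")
  names(state) <- sn
  src_idx <- match(vapply(spec$flows, `[[`, "", "source"), sn, nomatch = 0L)
  snk_idx <- match(vapply(spec$flows, `[[`, "", "sink"), sn, nomatch = 0L)
  rate_of <- vapply(spec$flows, `[[`, "", "rate")
  env <- make_eval_env(spec)

  for (i in 0:n) {
    row <- i + 1L
    stocks[row, ] <- state
    assign("t", times[row], envir = env)
    for (k in seq_along(sn)) assign(sn[k], state[[k]], envir = env)
    auxv <- tryCatch(eval_auxiliaries(spec, env, ord, parsed),
                     error = function(e) {
                       stop("at t = ", times[row], ": ", conditionMessage(e),
                            call. = FALSE)
                     })
    auxs[row, ] <- auxv
    nominal <- auxv[rate_of]
    res <- tryCatch(step_state(as.numeric(state), config$dt, as.numeric(nominal),
                               src_idx, snk_idx, fn),
                    error = function(e) {
                      stop("at t = ", times[row], ": ", conditionMessage(e),
                           call. = FALSE)
                    })
    flows[row, ] <- res$realized
    if (i < n) {
      state <- res$state
      names(state) <- sn
    }
  }

  structure(list(times = times, stocks = stocks, flows = flows,
                 auxiliaries = auxs,
                 units = list(
                   stocks = vapply(spec$stocks, `[[`, "", "unit"),
                   flows = rep("persons/year", length(fn)),
                   auxiliaries = vapply(spec$auxiliaries, `[[`, "", "unit")[
                     match(ord, aux_names(spec))]),
                 model = spec, config = config),
            class = "sd_trajectory")
}

#' @export
print.sd_trajectory <- function(x, ...) {
  cat("Trajectory of '", x$model$name, "': ",
      length(x$times), " points, ", x$times[1L], " to ",
      x$times[length(x$times)], "\n", sep = "")
  cat("  series: ", ncol(x$stocks), " stocks, ", ncol(x$flows), " flows, ",
      ncol(x$auxiliaries), " auxiliaries\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.sd_trajectory <- function(x, ...) {
  data.frame(time = x$times, x$stocks, x$flows, x$auxiliaries,
             check.names = FALSE)
}

## all series names of a trajectory, in stock/flow/aux order
trajectory_series <- function(traj) {
  c(colnames(traj$stocks), colnames(traj$flows), colnames(traj$auxiliaries))
}

get_series <- function(traj, series) {
  for (part in c("stocks", "flows", "auxiliaries")) {
    m <- traj[[part]]
    if (series %in% colnames(m)) return(m[, series])
  }
  stop("unknown series '", series, "'", call. = FALSE)
}

#' Read a series value at a given year
#'
#' Looks up a stock, flow or auxiliary at a year on the simulation grid.
#' For the CKD model's cumulative counters this is the quantity the study's
#' endpoint comparisons use (e.g. cumulative progression to stage 2 in 2022).
#'
#' @param traj An `sd_trajectory` from [simulate.sd_model()].
#' @param series Series name (stock, flow or auxiliary).
#' @param year Year; must lie on the time grid.
#' @return The series value at that year.
#' @export
endpoint <- function(traj, series, year) {
  stopifnot(inherits(traj, "sd_trajectory"))
  i <- which(abs(traj$times - year) < 1e-9)
  if (length(i) != 1L) {
    stop("year ", year, " is not on the simulation grid", call. = FALSE)
  }
  v <- get_series(traj, series)
  v[[i]]
}

#' Per-step mass-balance residuals of a trajectory
#'
#' For each step, compares the change in total stock content with the net
#' boundary flow over the step: residual_i = delta(total stocks) -
#' dt * (boundary inflow - boundary outflow), using the realized flow rates
#' recorded in the trajectory. For a model whose flows all connect declared
#' stocks the residuals are zero up to floating point; any larger residual
#' indicates a broken model or a trajectory not produced from `spec`.
#'
#' @param traj An `sd_trajectory`.
#' @param spec The [sd_model()] that produced it (defaults to the model
#'   stored in the trajectory).
#' @return Numeric vector of residuals, one per step (length
#'   `length(times) - 1`). Attribute `relative` holds residuals scaled by
#'   the total stock content.
#' @export
mass_balance <- function(traj, spec = traj$model) {
  stopifnot(inherits(traj, "sd_trajectory"), inherits(spec, "sd_model"))
  if (!identical(stock_names(spec), colnames(traj$stocks)) ||
      !identical(flow_names(spec), colnames(traj$flows))) {
    stop("trajectory does not match the given model", call. = FALSE)
  }
  dt <- diff(traj$times)
  total <- rowSums(traj$stocks)
  src <- vapply(spec$flows, `[[`, "", "source")
  snk <- vapply(spec$flows, `[[`, "", "sink")
  n <- length(traj$times) - 1L
  net_boundary <- numeric(n)
  if (any(src == BOUNDARY)) {
    net_boundary <- net_boundary +
      rowSums(traj$flows[seq_len(n), src == BOUNDARY, drop = FALSE])
  }
  if (any(snk == BOUNDARY)) {
    net_boundary <- net_boundary -
      rowSums(traj$flows[seq_len(n), snk == BOUNDARY, drop = FALSE])
  }
  res <- diff(total) - dt * net_boundary
  scale <- pmax(abs(total[-1L]), 1)
  structure(res, relative = res / scale)
}

#' Plot trajectory series
#'
#' Line plot of one or more series against time (base graphics).
#'
#' @param x An `sd_trajectory`.
#' @param series Character vector of series names; defaults to all stocks.
#' @param col Line colours, recycled across series.
#' @param ... Passed to [graphics::matplot()].
#' @return Invisibly, the plotted matrix.
#' @export
plot.sd_trajectory <- function(x, series = colnames(x$stocks),
                               col = seq_along(series), ...) {
  m <- vapply(series, function(s) get_series(x, s), numeric(length(x$times)))
  graphics::matplot(x$times, m, type = "l", lty = 1, col = col,
                    xlab = "year", ylab = "value", ...)
  graphics::legend("topleft", legend = series, col = col, lty = 1, bty = "n")
  invisible(m)
}
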