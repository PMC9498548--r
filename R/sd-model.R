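#' Declare a stock
#'
#' A stock is an accumulating state variable of a system dynamics model
#' (for example, persons in CKD stage 3). Stocks change only through the
#' flows attached to them.
#'
#' @param name Identifier, unique among the stocks of a model.
#' @param initial Initial value at the simulation start; must be >= 0.
#' @param unit Free-text unit label (default `"persons"`).
#' @return An object of class `sd_stock`.
#' @seealso [sd_model()], [sd_flow()], [sd_aux()]
#' @export
#' @examples
#' sd_stock("Population", 6910840)
sd_stock <- function(name, initial = 0, unit = "persons") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.numeric(initial), length(initial) == 1L)
  structure(list(name = name, initial = as.numeric(initial), unit = unit),
            class = "sd_stock")
}

#' Boundary marker for flows entering or leaving the model
#'
#' Flows with `BOUNDARY` as source or sink move quantity across the model
#' boundary (a source or a sink cloud in stock-flow notation).
#' @export
BOUNDARY <- "BOUNDARY"

#' Declare a flow
#'
#' A flow moves quantity between two stocks, or between a stock and the
#' model boundary, at a rate given by a named auxiliary (persons/year).
#'
#' @param name Identifier, unique among the flows of a model.
#' @param source Name of the source stock, or [BOUNDARY].
#' @param sink Name of the sink stock, or [BOUNDARY].
#' @param rate Name of the auxiliary whose value is the flow rate.
#' @return An object of class `sd_flow`.
#' @export
#' @examples
#' sd_flow("incidence", "Population", "Stage1", rate = "incidence_rate")
sd_flow <- function(name, source, sink, rate) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.character(source), is.character(sink),
            is.character(rate), length(rate) == 1L)
  if (identical(source, sink)) {
    stop("flow '", name, "': source and sink must differ", call. = FALSE)
  }
  structure(list(name = name, source = source, sink = sink, rate = rate),
            class = "sd_flow")
}

#' Declare an auxiliary variable
#'
#' An auxiliary is an algebraic intermediate recomputed at every time step
#' from parameters, stocks and other auxiliaries. Expressions are ordinary
#' arithmetic (`+ - * / ^`, parentheses, `min`, `max`, `exp`, `log`, ...)
#' over those names; the dependency graph among auxiliaries must be acyclic.
#'
#' @param name Identifier, unique among the auxiliaries of a model.
#' @param expr Expression as a character string, e.g.
#'   `"Population * diabetes_rate / 100"`.
#' @param unit Free-text unit label (e.g. `"persons/year"`, `"fraction"`).
#' @return An object of class `sd_aux`.
#' @export
sd_aux <- function(name, expr, unit = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name),
            is.character(expr), length(expr) == 1L)
  parsed <- tryCatch(parse(text = expr)[[1L]],
                     error = function(e) stop("auxiliary '", name,
                                              "': cannot parse expression: ",
                                              conditionMessage(e), call. = FALSE))
  structure(list(name = name, expr = expr, parsed = parsed, unit = unit),
            class = "sd_aux")
}

#' Assemble a stock-and-flow model
#'
#' Bundles stocks, flows, auxiliaries and a named parameter vector into a
#' simulatable model description. Construction does not validate; call
#' [validate_sd_model()] (simulation does so automatically).
#'
#' @param stocks List of [sd_stock()] objects.
#' @param flows List of [sd_flow()] objects.
#' @param auxiliaries List of [sd_aux()] objects.
#' @param parameters Named numeric vector or list of parameter values.
#' @param name Optional model name.
#' @return An object of class `sd_model`.
#' @seealso [simulate.sd_model()], [validate_sd_model()]
#' @export
#' @examples
#' m <- sd_model(
#'   stocks = list(sd_stock("S", 1000)),
#'   flows = list(sd_flow("decay", "S", BOUNDARY, rate = "decay_rate")),
#'   auxiliaries = list(sd_aux("decay_rate", "S * r / 100", "persons/year")),
#'   parameters = c(r = 10)
#' )
#' traj <- simulate(m, config = sim_config(0, 12, dt = 1 / 64))
#' endpoint(traj, "S", 12)
sd_model <- function(stocks, flows, auxiliaries, parameters = numeric(),
                     name = "model") {
  stopifnot(is.list(stocks), is.list(flows), is.list(auxiliaries))
  for (s in stocks) stopifnot(inherits(s, "sd_stock"))
  for (f in flows) stopifnot(inherits(f, "sd_flow"))
  for (a in auxiliaries) stopifnot(inherits(a, "sd_aux"))
  parameters <- unlist(parameters)
  if (length(parameters) && is.null(names(parameters))) {
    stop("parameters must be named", call. = FALSE)
  }
  structure(list(stocks = stocks, flows = flows, auxiliaries = auxiliaries,
                 parameters = parameters, name = name),
            class = "sd_model")
}

#' @export
print.sd_model <- function(x, ...) {
  cat("System dynamics model '", x$name, "'\n", sep = "")
  cat("  stocks:      ", length(x$stocks), "\n")
  cat("  flows:       ", length(x$flows), "\n")
  cat("  auxiliaries: ", length(x$auxiliaries), "\n")
  cat("  parameters:  ", length(x$parameters), "\n")
  invisible(x)
}

#' @export
summary.sd_model <- function(object, ...) {
  rep <- validate_sd_model(object)
  print(object)
  if (nrow(rep) == 0L) {
    cat("  validation:   OK\n")
  } else {
    cat("  validation:  ", nrow(rep), "finding(s)\n")
    print(rep)
  }
  invisible(rep)
}

stock_names <- function(spec) vapply(spec$stocks, `[[`, "", "name")
flow_names  <- function(spec) vapply(spec$flows, `[[`, "", "name")
aux_names   <- function(spec) vapply(spec$auxiliaries, `[[`, "", "name")

## names an auxiliary refers to, restricted to other auxiliaries
aux_deps <- function(spec) {
  an <- aux_names(spec)
  deps <- lapply(spec$auxiliaries, function(a) intersect(all.vars(a$parsed), an))
  names(deps) <- an
  deps
}

finding <- function(code, message) {
  data.frame(code = code, message = message, stringsAsFactors = FALSE)
}

#' Validate a stock-and-flow model
#'
#' Checks every structural invariant a simulatable model must satisfy and
#' reports all violations at once; it never throws. An empty report means
#' the model can be simulated.
#'
#' Checked: unique stock/flow/auxiliary names, non-negative initial stock
#' values, flow endpoints naming declared stocks (or [BOUNDARY]), flow rates
#' naming declared auxiliaries, acyclic auxiliary dependencies, and
#' auxiliary expressions referring only to known names (stocks, parameters,
#' auxiliaries, the time variable `t`, and basic math functions).
#'
#' @param spec An [sd_model()].
#' @return A data frame with columns `code` and `message`, one row per
#'   violated invariant (zero rows if the model is well formed).
#' @export
validate_sd_model <- function(spec) {
  stopifnot(inherits(spec, "sd_model"))
  rep <- finding(character(), character())
  sn <- stock_names(spec)
  fn <- flow_names(spec)
  an <- aux_names(spec)

  for (set in list(c("stock", "sn"), c("flow", "fn"), c("auxiliary", "an"))) {
    nm <- switch(set[[1L]], stock = sn, flow = fn, auxiliary = an)
    dup <- unique(nm[duplicated(nm)])
    for (d in dup) {
      rep <- rbind(rep, finding("duplicate_name",
                                paste0("duplicate ", set[[1L]], " name '", d, "'")))
    }
  }
  shared <- intersect(sn, an)
  for (d in shared) {
    rep <- rbind(rep, finding("duplicate_name",
                              paste0("name '", d, "' used for both a stock and an auxiliary")))
  }
  for (s in spec$stocks) {
    if (!is.finite(s$initial) || s$initial < 0) {
      rep <- rbind(rep, finding("negative_initial",
                                paste0("stock '", s$name,
                                       "' has negative or non-finite initial value ",
                                       s$initial)))
    }
  }
  for (f in spec$flows) {
    for (end in c("source", "sink")) {
      v <- f[[end]]
      if (!identical(v, BOUNDARY) && !(v %in% sn)) {
        rep <- rbind(rep, finding("dangling_endpoint",
                                  paste0("flow '", f$name, "' ", end,
                                         " names undeclared stock '", v, "'")))
      }
    }
    if (!(f$rate %in% an)) {
      rep <- rbind(rep, finding("unresolved_rate",
                                paste0("flow '", f$name,
                                       "' rate names undeclared auxiliary '",
                                       f$rate, "'")))
    }
  }
  cyc <- aux_cycle(spec)
  if (!is.null(cyc)) {
    rep <- rbind(rep, finding("aux_cycle",
                              paste0("cyclic auxiliary dependency: ",
                                     paste(cyc, collapse = " -> "))))
  }
  known <- c(sn, an, names(spec$parameters), "t", "pi")
  for (a in spec$auxiliaries) {
    unk <- setdiff(all.vars(a$parsed), known)
    for (u in unk) {
      rep <- rbind(rep, finding("unknown_symbol",
                                paste0("auxiliary '", a$name,
                                       "' refers to unknown name '", u, "'")))
    }
  }
  rep
}

## returns NULL if acyclic, otherwise one cycle as a character vector
aux_cycle <- function(spec) {
  deps <- aux_deps(spec)
  state <- new.env(parent = emptyenv())
  found <- NULL
  visit <- function(n, path) {
    if (!is.null(found)) return()
    st <- if (exists(n, envir = state, inherits = FALSE)) get(n, envir = state) else 0L
    if (st == 1L) {
      i <- match(n, path)
      found <<- c(path[i:length(path)], n)
      return()
    }
    if (st == 2L) return()
    assign(n, 1L, envir = state)
    for (d in deps[[n]]) visit(d, c(path, n))
    assign(n, 2L, envir = state)
  }
  for (n in names(deps)) visit(n, character())
  found
}

#' Topologically order the auxiliaries of a model
#'
#' Returns the auxiliary names ordered so that every auxiliary appears
#' after all auxiliaries it depends on; this is the evaluation order used
#' at every simulation step.
#'
#' @param spec An [sd_model()].
#' @return Character vector of auxiliary names in dependency order.
#'   Errors, naming the cycle, if the dependency graph is cyclic.
#' @export
order_auxiliaries <- function(spec) {
  stopifnot(inherits(spec, "sd_model"))
  cyc <- aux_cycle(spec)
  if (!is.null(cyc)) {
    stop("cyclic auxiliary dependency: ", paste(cyc, collapse = " -> "),
         call. = FALSE)
  }
  deps <- aux_deps(spec)
  remaining <- names(deps)
  ordered <- character()
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(n) {
      all(deps[[n]] %in% ordered)
    }, logical(1L))]
    # declaration order breaks ties, keeping the result deterministic
    ordered <- c(ordered, ready)
    remaining <- setdiff(remaining, ready)
  }
  ordered
}
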