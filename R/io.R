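## Trajectory CSV layout: one row per grid point, first column
## "time (year)", then one column per series with header
## "<name> (<kind>; <unit>)" where kind is stock/flow/aux. Numbers are
## written with "%.17g" (lossless for doubles), '.' decimal point, Unix
## newlines, so identical runs produce byte-identical files.

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[!is.finite(x)] <- as.character(x[!is.finite(x)])
  out
}

#' Write a trajectory to CSV
#'
#' @param traj An `sd_trajectory`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @seealso [read_trajectory_csv()]
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "sd_trajectory"))
  hdr <- c("time (year)",
           sprintf("%s (stock; %s)", colnames(traj$stocks),
                   traj$units$stocks),
           sprintf("%s (flow; %s)", colnames(traj$flows), traj$units$flows),
           sprintf("%s (aux; %s)", colnames(traj$auxiliaries),
                   traj$units$auxiliaries))
  m <- cbind(traj$times, traj$stocks, traj$flows, traj$auxiliaries)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(hdr, collapse = ","), con, sep = "\n")
  if (nrow(m) > 0L) {
    body <- apply(m, 1L, function(r) paste(fmt_num(r), collapse = ","))
    writeLines(body, con, sep = "\n")
  }
  invisible(path)
}

#' Read a trajectory written by [write_trajectory_csv()]
#'
#' Restores times and all series at full precision. The result carries no
#' model (`model` is `NULL`); [endpoint()] and [get_series] work as usual.
#'
#' @param path CSV path.
#' @return An `sd_trajectory`.
#' @export
read_trajectory_csv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1L) stop("empty file: ", path, call. = FALSE)
  hdr <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  if (length(lines) == 1L) {
    stop("trajectory file '", path, "' has a header but no data rows",
         call. = FALSE)
  }
  pat <- "^(.*) \\((stock|flow|aux); (.*)\\)$"
  meta <- regmatches(hdr[-1L], regexec(pat, hdr[-1L]))
  if (any(lengths(meta) != 4L)) {
    stop("malformed trajectory header in ", path, call. = FALSE)
  }
  nm <- vapply(meta, `[[`, "", 2L)
  kind <- vapply(meta, `[[`, "", 3L)
  unit <- vapply(meta, `[[`, "", 4L)
  m <- do.call(rbind, lapply(lines[-1L], function(ln) {
    as.numeric(strsplit(ln, ",", fixed = TRUE)[[1L]])
  }))
  pick <- function(k) {
    sel <- kind == k
    out <- m[, c(FALSE, sel), drop = FALSE]
    colnames(out) <- nm[sel]
    out
  }
  structure(list(times = m[, 1L],
                 stocks = pick("stock"), flows = pick("flow"),
                 auxiliaries = pick("aux"),
                 units = list(stocks = unit[kind == "stock"],
                              flows = unit[kind == "flow"],
                              auxiliaries = unit[kind == "aux"]),
                 model = NULL, config = NULL),
            class = "sd_trajectory")
}

#' Export a stock-flow model to XMILE
#'
#' Writes the model as an XMILE (OASIS system dynamics interchange) XML
#' document: stocks with initial values and attached inflows/outflows,
#' flows with their rate equations, auxiliaries with their expressions,
#' and Euler `sim_specs` from the configuration. Import is not supported.
#'
#' @param spec An [sd_model()].
#' @param path Output path.
#' @param config Optional [sim_config()] for the `sim_specs` block.
#' @return Invisibly, the path.
#' @export
write_xmile <- function(spec, path, config = NULL) {
  stopifnot(inherits(spec, "sd_model"))
  doc <- xml2::xml_new_root(
    "xmile", version = "1.0",
    xmlns = "http://docs.oasis-open.org/xmile/ns/XMILE/v1.0")
  hdr <- xml2::xml_add_child(doc, "header")
  xml2::xml_add_child(hdr, "name", spec$name)
  xml2::xml_add_child(hdr, "vendor", "ckdflow")
  xml2::xml_add_child(hdr, "product", "ckdflow",
                      version = as.character(utils::packageVersion("ckdflow")))
  if (!is.null(config)) {
    ss <- xml2::xml_add_child(doc, "sim_specs", method = "Euler",
                              time_units = "year")
    xml2::xml_add_child(ss, "start", format(config$t_start))
    xml2::xml_add_child(ss, "stop", format(config$t_end))
    xml2::xml_add_child(ss, "dt", format(config$dt))
  }
  model <- xml2::xml_add_child(doc, "model")
  vars <- xml2::xml_add_child(model, "variables")
  for (s in spec$stocks) {
    st <- xml2::xml_add_child(vars, "stock", name = s$name)
    xml2::xml_add_child(st, "eqn", format(s$initial))
    for (f in spec$flows) {
      if (identical(f$sink, s$name)) xml2::xml_add_child(st, "inflow", f$name)
      if (identical(f$source, s$name)) xml2::xml_add_child(st, "outflow", f$name)
    }
    xml2::xml_add_child(st, "units", s$unit)
  }
  for (f in spec$flows) {
    fl <- xml2::xml_add_child(vars, "flow", name = f$name)
    xml2::xml_add_child(fl, "eqn", f$rate)
    xml2::xml_add_child(fl, "units", "persons/year")
  }
  for (a in spec$auxiliaries) {
    ax <- xml2::xml_add_child(vars, "aux", name = a$name)
    xml2::xml_add_child(ax, "eqn", a$expr)
    if (nzchar(a$unit)) xml2::xml_add_child(ax, "units", a$unit)
  }
  for (p in names(spec$parameters)) {
    ax <- xml2::xml_add_child(vars, "aux", name = p)
    xml2::xml_add_child(ax, "eqn", format(spec$parameters[[p]]))
  }
  xml2::write_xml(doc, path)
  invisible(path)
}

#' Write a run manifest
#'
#' Records everything needed to reproduce a run byte-for-byte: the full
#' parameter and simulation-configuration snapshot, the scenario name and
#' overrides (if any), the package version, the seed and the output paths.
#'
#' @param path Manifest path (JSON).
#' @param params A [ckd_parameters()] object.
#' @param config A [sim_config()].
#' @param scen Optional [scenario()].
#' @param outputs Character vector of output file paths.
#' @param seed Optional integer seed (recorded; the engine is
#'   deterministic).
#' @return Invisibly, the path.
#' @seealso [rerun_manifest()]
#' @export
write_manifest <- function(path, params, config, scen = NULL,
                           outputs = character(), seed = NULL) {
  if (!inherits(params, "ckd_params")) params <- ckd_parameters(params)
  man <- list(
    tool = "ckdflow",
    version = as.character(utils::packageVersion("ckdflow")),
    seed = seed,
    parameters = unclass(params)[ckd_param_fields()],
    simulation = list(t_start = config$t_start, t_end = config$t_end,
                      dt = config$dt),
    scenario = if (!is.null(scen)) {
      list(name = scen$name, overrides = scen$overrides)
    },
    outputs = as.list(outputs)
  )
  jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Re-run a manifest
#'
#' Reproduces the CSV outputs described by a manifest. Because the engine
#' is deterministic and the CSV writer is byte-stable, re-running yields
#' bitwise-identical files.
#'
#' @param manifest_path Path to a manifest written by [write_manifest()].
#' @param out_dir Directory for the regenerated outputs (defaults to the
#'   manifest's recorded paths).
#' @return Character vector of the paths written.
#' @export
rerun_manifest <- function(manifest_path, out_dir = NULL) {
  man <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  params <- ckd_parameters(as.list(man$parameters))
  config <- sim_config(man$simulation$t_start, man$simulation$t_end,
                       man$simulation$dt)
  outputs <- unlist(man$outputs)
  if (!is.null(out_dir)) {
    outputs <- file.path(out_dir, basename(outputs))
  }
  if (!is.null(man$scenario) && length(man$scenario)) {
    scen <- scenario(man$scenario$name, as.list(man$scenario$overrides))
    pair <- run_pair(params, scen, config)
    stopifnot(length(outputs) == 2L)
    write_trajectory_csv(pair$base, outputs[1L])
    write_trajectory_csv(pair$scenario, outputs[2L])
  } else {
    traj <- simulate(build_ckd_model(params), config = config)
    stopifnot(length(outputs) == 1L)
    write_trajectory_csv(traj, outputs[1L])
  }
  outputs
}
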