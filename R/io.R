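## Configuration and serialization: YAML run configs, time-course CSV/JSON.

CONFIG_KEYS <- c("preset", "scenario", "sensor", "duration", "dt",
                 "record_stride", "seed", "output", "params")
PERT_KEYS <- c("parameter", "shape", "onset", "value", "amplitude",
               "frequency", "phase", "half_time")

#' Load a run configuration
#'
#' Reads a YAML configuration describing a simulation run: an optional
#' parameter override block (`params:`), either a preset name (`preset:`)
#' or an inline scenario (`scenario:` with `A_mem_mode`, `dm_mode` and a
#' `perturbations:` list), the sensor switch, duration, step and output
#' paths. Unknown keys are rejected with their paths. An empty file yields
#' the standard parameter set with no perturbation.
#'
#' @param path Path to a YAML file.
#' @return A `run_config` list with validated, default-filled fields:
#'   `params` (a [tip_params()]), `scenario`, `sensor`, `duration`, `dt`,
#'   `record_stride`, `seed`, `output`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), CONFIG_KEYS)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)

  par_over <- raw$params %||% list()
  bad <- setdiff(names(par_over), names(formals(tip_params)))
  if (length(bad))
    stop("unknown parameter(s) in params: ",
         paste(paste0("params.", bad), collapse = ", "), call. = FALSE)
  if (!is.null(raw$dt)) par_over$dt <- raw$dt
  params <- do.call(tip_params, par_over)

  if (!is.null(raw$preset) && !is.null(raw$scenario))
    stop("give either 'preset' or 'scenario', not both", call. = FALSE)

  sensor <- TRUE
  scen <- NULL
  if (!is.null(raw$preset)) {
    ps <- preset_scenario(raw$preset, params)
    scen <- ps$scenario
    sensor <- ps$sensor
  } else if (!is.null(raw$scenario)) {
    sc <- raw$scenario
    bad <- setdiff(names(sc), c("A_mem_mode", "dm_mode", "perturbations"))
    if (length(bad))
      stop("unknown config key(s): ",
           paste(paste0("scenario.", bad), collapse = ", "), call. = FALSE)
    perts <- lapply(sc$perturbations %||% list(), function(p) {
      bad <- setdiff(names(p), PERT_KEYS)
      if (length(bad))
        stop("unknown config key(s): ",
             paste(paste0("scenario.perturbations.", bad), collapse = ", "),
             call. = FALSE)
      do.call(perturbation, p)
    })
    scen <- scenario(perts,
                     A_mem_mode = sc$A_mem_mode %||% "osmotic_zone",
                     dm_mode = sc$dm_mode %||% "fixed")
  }
  if (!is.null(raw$sensor)) sensor <- isTRUE(raw$sensor)

  cfg <- list(params = params, scenario = scen, sensor = sensor,
              duration = raw$duration %||% 2000,
              dt = params$dt,
              record_stride = as.integer(raw$record_stride %||% 1L),
              seed = raw$seed %||% 1L,
              output = raw$output %||% NULL)
  stopifnot(cfg$duration >= cfg$dt)
  class(cfg) <- "run_config"
  cfg
}

#' Execute a run configuration
#'
#' @param cfg A [load_config()] result.
#' @return The `tip_timecourse`.
#' @export
run_config <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  run(cfg$params, cfg$scenario, sensor = cfg$sensor,
      duration = cfg$duration, record_stride = cfg$record_stride)
}

#' Serialize a time course to CSV plus JSON metadata
#'
#' One row per sample with unit-suffixed column headers; the JSON sidecar
#' (`<path>.json`) carries the outcome, burst time, parameters and
#' scenario description.
#'
#' @param tc A `tip_timecourse`.
#' @param path CSV path.
#' @export
write_timecourse <- function(tc, path) {
  stopifnot(inherits(tc, "tip_timecourse"))
  d <- as.data.frame(tc)
  names(d) <- c("t_s", "L_um", "Pi_i_MPa", "dPi_MPa", "dP_MPa",
                "dL_dt_um_s", "L_wall_um", "dVwall_dt_um3_s",
                "eta_MPa_s", "L_perm_um")
  utils::write.csv(d, path, row.names = FALSE)
  p <- attr(tc, "params")
  scen <- attr(tc, "scenario")
  meta <- list(
    outcome = attr(tc, "outcome"),
    burst_time_s = attr(tc, "burst_time"),
    dt_s = attr(tc, "dt"),
    record_stride = attr(tc, "record_stride"),
    sensor = unclass(attr(tc, "sensor"))[c("input", "output", "gain",
                                           "half_time", "clamp")],
    scenario = if (is.null(scen)) NULL else list(
      name = scen$name, A_mem_mode = scen$A_mem_mode,
      dm_mode = scen$dm_mode,
      perturbations = lapply(scen$perturbations, unclass)),
    params = unclass(p))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_timecourse
#' @export
read_timecourse <- function(path) {
  d <- utils::read.csv(path)
  names(d) <- c("t", "L", "Pi_i", "dPi", "dP", "dL_dt", "L_wall",
                "dVwall_dt", "eta", "L_perm")
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  structure(d, class = c("tip_timecourse", "data.frame"),
            outcome = meta$outcome %||% "unknown",
            burst_time = meta$burst_time_s %||% NA_real_,
            dt = meta$dt_s %||% NA_real_,
            record_stride = meta$record_stride %||% 1L,
            params = meta$params, scenario = meta$scenario,
            sensor = meta$sensor)
}
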