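## Sensor couplings: which intensive variable the cell senses and which
## rate parameter the signal controls.

SENSOR_INPUTS <- c("water_potential", "osmotic", "turgor", "none")
SENSOR_OUTPUTS <- c("wall_extrusion", "solute_rate", "hardening")

#' Specify a sensor coupling
#'
#' A sensor senses one intensive variable -- the water potential difference
#' \eqn{\Delta\Pi - \Delta P}, the osmotic gradient \eqn{\Delta\Pi}, or the
#' turgor \eqn{\Delta P} -- and sets one rate parameter: pectin wall extrusion
#' \eqn{dV_{wall}/dt}, solute accumulation \eqn{dm/dt}, or the hardening rate
#' \eqn{\alpha}. Input `"none"` leaves the output at its fixed baseline (no
#' feedback). The default coupling, water potential controlling wall
#' extrusion, is the osmosensor at the heart of the model.
#'
#' The sensor population is taken to be distributed over the osmotically
#' active membrane, so the total output scales with `A_mem` relative to the
#' reference area; `gain` is the gain at the reference area. When `gain` is
#' `NULL` it is auto-calibrated so the coupling reproduces the baseline
#' steady state of the supplied parameter set.
#'
#' @param input One of `"water_potential"`, `"osmotic"`, `"turgor"`, `"none"`.
#' @param output One of `"wall_extrusion"`, `"solute_rate"`, `"hardening"`.
#' @param gain Coupling gain in output units per MPa; `NULL` to auto-calibrate
#'   at run time.
#' @param half_time Response half-time of the signalling chain, s; `NULL`
#'   uses the parameter set's `ht_sensor`.
#' @param clamp Clamp the sensed signal at zero (default), so output is only
#'   generated while the signal is positive.
#' @return A `sensor_spec` object.
#' @examples
#' water_potential_sensor()          # the default osmosensor
#' sensor_spec("osmotic", "hardening")
#' @export
sensor_spec <- function(input = "water_potential", output = "wall_extrusion",
                        gain = NULL, half_time = NULL, clamp = TRUE) {
  input <- match.arg(input, SENSOR_INPUTS)
  output <- match.arg(output, SENSOR_OUTPUTS)
  if (!is.null(gain) && gain < 0) stop("gain must be >= 0", call. = FALSE)
  structure(list(input = input, output = output, gain = gain,
                 half_time = half_time, clamp = clamp),
            class = "sensor_spec")
}

#' @rdname sensor_spec
#' @export
water_potential_sensor <- function(gain = NULL, half_time = NULL) {
  sensor_spec("water_potential", "wall_extrusion", gain, half_time)
}

#' @rdname sensor_spec
#' @export
no_sensor <- function() sensor_spec("none", "wall_extrusion")

#' @export
print.sensor_spec <- function(x, ...) {
  if (x$input == "none") {
    cat("Sensor: none (all rates at fixed baselines)\n")
  } else {
    sig <- switch(x$input, water_potential = "(dPi - dP)",
                  osmotic = "dPi", turgor = "dP")
    cat(sprintf("Sensor: %s -> %s, gain %s, clamp %s\n", sig, x$output,
                if (is.null(x$gain)) "auto" else signif(x$gain, 4), x$clamp))
  }
  invisible(x)
}

## Baseline (calibration point) values of each sensed signal and each
## controlled output for a parameter set.
baseline_signal <- function(input, params) {
  switch(input,
         water_potential = params$dPi_target - params$dP_target,
         osmotic = params$dPi_target,
         turgor = params$dP_target,
         none = NA_real_)
}

baseline_output <- function(output, params) {
  switch(output,
         wall_extrusion = params$dVwall_baseline,
         solute_rate = params$dm_dt,
         hardening = params$alpha)
}

#' Auto-calibrate a sensor gain
#'
#' Solves the gain so that at the unperturbed steady state the sensor
#' reproduces the baseline value of its output (like-for-like baselines
#' across all couplings in the stability screen).
#'
#' @param spec A [sensor_spec()].
#' @param params A [tip_params()] object.
#' @return The spec with `gain` and `half_time` filled in.
#' @export
calibrate_gain <- function(spec, params) {
  stopifnot(inherits(spec, "sensor_spec"))
  if (is.null(spec$half_time)) spec$half_time <- params$ht_sensor
  if (spec$input == "none" || !is.null(spec$gain)) return(spec)
  spec$gain <- baseline_output(spec$output, params) /
    baseline_signal(spec$input, params)
  spec
}

#' Evaluate a sensor's controlled rate
#'
#' Output is `gain * area_factor * signal`, with the signal clamped at zero
#' when the clamp flag is set; input `"none"` returns the baseline unchanged.
#' `area_factor` is `A_mem` relative to the reference membrane area, carrying
#' the assumption that sensors are distributed over the osmotic zone.
#'
#' @param spec A calibrated [sensor_spec()].
#' @param dPi,dP Current osmotic and turgor pressure differences, MPa.
#' @param baseline Baseline value of the controlled output.
#' @param area_factor Ratio of current to reference osmotic membrane area.
#' @return Controlled rate in the output's units.
#' @export
sensor_output <- function(spec, dPi, dP, baseline, area_factor = 1) {
  stopifnot(is.finite(dPi), is.finite(dP))
  if (spec$input == "none") return(baseline)
  if (is.null(spec$gain)) stop("sensor gain not calibrated", call. = FALSE)
  signal <- switch(spec$input,
                   water_potential = dPi - dP,
                   osmotic = dPi,
                   turgor = dP)
  if (isTRUE(spec$clamp)) signal <- max(0, signal)
  spec$gain * area_factor * signal
}

#' Enumerate the nine candidate sensor couplings
#'
#' Cartesian product of the three sensed inputs and three controlled outputs,
#' plus a no-sensor control, each with auto-calibrated gain.
#'
#' @param params A [tip_params()] object used for gain calibration.
#' @return Named list of 10 `sensor_spec` objects (9 couplings + `"none"`).
#' @export
enumerate_couplings <- function(params = tip_params()) {
  specs <- list()
  for (inp in setdiff(SENSOR_INPUTS, "none")) {
    for (out in SENSOR_OUTPUTS) {
      nm <- paste(inp, out, sep = "->")
      specs[[nm]] <- calibrate_gain(sensor_spec(inp, out), params)
    }
  }
  specs[["none"]] <- calibrate_gain(no_sensor(), params)
  specs
}
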