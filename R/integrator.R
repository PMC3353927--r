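## Fixed-step time advance of the model (forward Euler at dt = 0.4 s, the
## scheme the model was designed around), with exponential smoothing of the
## expansion rate and sensor output, burst detection and trajectory
## recording.

#' Exponential relaxation toward a target
#'
#' One smoothing update with a given half-time:
#' `current + (target - current) * (1 - 2^(-dt/half_time))`. Used for the
#' tip expansion rate, the sensor signalling chain, and step parameter
#' changes.
#'
#' @param current Current value.
#' @param target Target value.
#' @param half_time Half-time of the relaxation, s.
#' @param dt Time step, s.
#' @return The relaxed value.
#' @examples
#' exp_relax(0, 1, 0.2, 0.4)  # 0.75
#' @export
exp_relax <- function(current, target, half_time, dt) {
  stopifnot(half_time > 0, dt > 0)
  current + (target - current) * (1 - 2^(-dt / half_time))
}

#' Initial model state
#'
#' A stationary tube of length `L_init` loaded with solute at water
#' equilibrium: the internal osmotic pressure starts at
#' `Pi_o + dPi_init`, the apical film at the calibrated thickness, and the
#' extrusion machinery at the baseline rate. Turgor is algebraic, so growth
#' develops as soon as the first step lets the viscous film yield.
#'
#' @param params A [tip_params()] object.
#' @param sensor A calibrated [sensor_spec()] (sets the initial value of the
#'   smoothed sensor output).
#' @return A `tip_state` list with fields `t`, `L`, `V`, `m`, `Pi_i`,
#'   `L_wall`, `E_smooth`, `ctrl_smooth`, `dVwall_smooth`, `burst`.
#' @export
new_state <- function(params, sensor = no_sensor()) {
  Pi_o <- vant_hoff_pressure(params$C_o, params$temperature)
  Pi_i <- Pi_o + params$dPi_init
  V <- pi * params$r^2 * params$L_init
  m <- Pi_i * V / rt_um3(params$temperature)
  ctrl0 <- if (sensor$input == "none") baseline_output(sensor$output, params)
           else baseline_output(sensor$output, params)
  state <- list(t = 0, L = params$L_init, V = V, m = m, Pi_i = Pi_i,
                L_wall = params$L_wall_target,
                E_smooth = 0,
                dP_smooth = params$dPi_init,   # water equilibrium: dP = dPi
                ctrl_smooth = ctrl0,
                dVwall_smooth = params$dVwall_baseline,
                burst = FALSE)
  class(state) <- "tip_state"
  state
}

## Derived quantities and rates for one step; shared by step() and run().
## Returns the updated state and the record of the step.
advance <- function(state, params, scen, sensor, t) {
  p <- effective_params(params, scen, t, L = state$L)
  dt <- p$dt
  Pi_o <- vant_hoff_pressure(p$C_o, p$temperature)
  dPi <- state$Pi_i - Pi_o
  G <- p$P_os_bar * p$A_mem

  sensed <- sensor$input != "none"
  alpha_eff <- if (sensed && sensor$output == "hardening")
    max(0, state$ctrl_smooth) else p$alpha
  dVwall_now <- if (sensed && sensor$output == "wall_extrusion")
    max(0, state$ctrl_smooth) else p$dVwall_baseline
  dm_eff <- if (sensed && sensor$output == "solute_rate")
    max(0, state$ctrl_smooth) else p$dm_dt
  if (!is.null(scen) && identical(scen$dm_mode, "per_area"))
    dm_eff <- dm_eff * p$A_mem / params$A_mem_ref

  eta <- wall_viscosity(p$eta_0, alpha_eff, dVwall_now, p$A_tip,
                        state$L_wall, p$eta_cap_factor)
  ## Turgor is algebraic: the rearranged influx law evaluated at the current
  ## smoothed expansion throughput (incompressible cytoplasm swallows volume
  ## at rate r*E/2). The one-step lag between pressure and expansion is what
  ## admits the thin-film oscillatory instability that bursts the tip; the
  ## smoothing half-times damp it at ordinary operating points.
  dP_eq8 <- dPi - (p$r * state$E_smooth / 2) / G
  dP_mech <- exp_relax(state$dP_smooth, dP_eq8, p$ht_turgor, dt)
  E_target <- tip_expansion_rate(tip_tension(dP_mech, p$r, p$gamma), eta,
                                 state$L_wall, p$A_tip)
  E_new <- exp_relax(state$E_smooth, E_target, p$ht_expansion, dt)
  dL_dt <- E_new / (2 * pi * p$r)
  dV_dt <- pi * p$r^2 * dL_dt
  if (dPi < 0) {             # plasmolytic efflux: no expansion, water leaves
    dV_dt <- dV_dt + G * dPi
    dL_dt <- dV_dt / (pi * p$r^2)
  }
  dP_rec <- dPi - dV_dt / G            # Eq. 8 identity

  area_factor <- p$A_mem / params$A_mem_ref
  base_out <- baseline_output(sensor$output, p)
  target_out <- sensor_output(sensor, dPi, dP_rec, base_out, area_factor)
  ctrl_new <- if (sensed)
    exp_relax(state$ctrl_smooth, target_out, sensor$half_time, dt)
  else target_out

  dLwall_dt <- wall_thickness_rate(dVwall_now, E_new, p$A_tip, state$L_wall)

  L_new <- state$L + dL_dt * dt
  m_new <- state$m + dm_eff * dt
  Lw_new <- state$L_wall + dLwall_dt * dt
  V_new <- pi * p$r^2 * L_new
  Pi_new <- rt_um3(p$temperature) * m_new / V_new

  vals <- c(L_new, m_new, Lw_new, Pi_new, E_new, ctrl_new)
  if (!all(is.finite(vals)))
    stop("non-finite state at t = ", t, " s: ",
         paste(sprintf("%s=%g", c("L", "m", "L_wall", "Pi_i", "E", "ctrl"),
                       vals), collapse = ", "), call. = FALSE)

  burst <- Lw_new <= p$burst_threshold
  state$t <- t + dt
  state$L <- L_new
  state$V <- V_new
  state$m <- m_new
  state$Pi_i <- Pi_new
  state$L_wall <- max(Lw_new, 0)
  state$E_smooth <- E_new
  state$dP_smooth <- dP_mech
  state$ctrl_smooth <- ctrl_new
  state$dVwall_smooth <- dVwall_now
  state$burst <- burst

  rec <- c(t = t + dt, L = L_new, Pi_i = Pi_new, dPi = dPi, dP = dP_rec,
           dL_dt = dL_dt, L_wall = state$L_wall, dVwall_dt = dVwall_now,
           eta = eta, L_perm = p$L_perm)
  list(state = state, rec = rec)
}

#' Advance the model by one time step
#'
#' Applies the scenario-effective parameters at time `t`, solves the
#' algebraic turgor balance, evaluates the sensor, relaxes the smoothed
#' expansion rate and sensor output, and forward-Euler updates length,
#' solute content and wall thickness. Sets the burst flag when the film
#' thickness falls to the bursting threshold.
#'
#' @param state A `tip_state` (not burst).
#' @param params A [tip_params()] object.
#' @param scen A [scenario()] or `NULL`.
#' @param sensor A calibrated [sensor_spec()].
#' @param t Current time, s.
#' @return The updated `tip_state` at `t + dt`.
#' @export
step <- function(state, params, scen = NULL,
                 sensor = calibrate_gain(water_potential_sensor(), params),
                 t = state$t) {
  if (isTRUE(state$burst)) stop("cannot step a burst state", call. = FALSE)
  advance(state, params, scen, sensor, t)$state
}

resolve_sensor <- function(sensor, params) {
  if (isTRUE(sensor)) sensor <- water_potential_sensor()
  if (is.null(sensor) || isFALSE(sensor)) sensor <- no_sensor()
  stopifnot(inherits(sensor, "sensor_spec"))
  calibrate_gain(sensor, params)
}

#' Run a simulation
#'
#' Integrates the model from the standard stationary initial condition for
#' `duration` seconds (or until the tip bursts), recording every
#' `record_stride`-th step, and labels the outcome: `"burst"` (threshold
#' hit; pressure gradients recorded as zero at the burst sample),
#' `"arrest"` (steady with growth below 1% of the reference rate),
#' `"steady"` (all trailing-window drifts below tolerance) or `"unstable"`.
#'
#' @param params A [tip_params()] object.
#' @param scen A [scenario()], a preset name (see [preset_names()]), or
#'   `NULL` for the unperturbed baseline.
#' @param sensor A [sensor_spec()], or `TRUE` for the standard
#'   water-potential osmosensor, or `FALSE`/`NULL` for none. When a preset
#'   name is given as `scen`, the preset's sensor choice is used unless
#'   `sensor` is supplied explicitly.
#' @param duration Simulated time, s.
#' @param record_stride Record every n-th step.
#' @param steady_window,steady_tol Trailing window (s) and relative drift
#'   tolerance for the steady-state flag.
#' @param state0 Optional initial `tip_state` (default [new_state()]): use
#'   to start a run on the growing manifold (e.g. with the tip expansion
#'   throughput already balancing extrusion) instead of from a stationary
#'   tube.
#' @return A `tip_timecourse`: a data frame with columns `t`, `L`, `Pi_i`,
#'   `dPi`, `dP`, `dL_dt`, `L_wall`, `dVwall_dt`, `eta`, `L_perm`, with the
#'   outcome, burst time, parameters, scenario and sensor attached as
#'   attributes.
#' @examples
#' \donttest{
#' tc <- run(tip_params(), duration = 600)
#' summary(tc)
#' }
#' @export
run <- function(params = tip_params(), scen = NULL, sensor = TRUE,
                duration = 2000, record_stride = 1L,
                steady_window = 100, steady_tol = 1e-3, state0 = NULL) {
  stopifnot(inherits(params, "tip_params"), duration > 0)
  if (is.character(scen)) {
    preset <- preset_scenario(scen, params)
    if (missing(sensor)) sensor <- preset$sensor
    scen <- preset$scenario
  }
  sensor <- resolve_sensor(sensor, params)
  state <- if (is.null(state0)) new_state(params, sensor) else state0

  dt <- params$dt
  n_steps <- ceiling(duration / dt)
  record_stride <- max(1L, as.integer(record_stride))
  n_rec <- floor(n_steps / record_stride) + 1L
  out <- matrix(NA_real_, nrow = n_rec + 1L, ncol = 10,
                dimnames = list(NULL, c("t", "L", "Pi_i", "dPi", "dP",
                                        "dL_dt", "L_wall", "dVwall_dt",
                                        "eta", "L_perm")))
  Pi_o0 <- vant_hoff_pressure(params$C_o, params$temperature)
  out[1L, ] <- c(0, state$L, state$Pi_i, state$Pi_i - Pi_o0,
                 state$Pi_i - Pi_o0, 0, state$L_wall,
                 state$dVwall_smooth, NA, params$L_perm)
  k <- 1L
  burst_time <- NA_real_
  for (i in seq_len(n_steps)) {
    res <- advance(state, params, scen, sensor, (i - 1L) * dt)
    state <- res$state
    if (state$burst) {
      burst_time <- state$t
      rec <- res$rec
      rec[c("dPi", "dP")] <- 0          # gradients collapse at burst
      k <- k + 1L
      out[k, ] <- rec
      break
    }
    if (i %% record_stride == 0L) {
      k <- k + 1L
      out[k, ] <- res$rec
    }
  }
  out <- as.data.frame(out[seq_len(k), , drop = FALSE])

  tc <- structure(out,
                  class = c("tip_timecourse", "data.frame"),
                  params = params, scenario = scen, sensor = sensor,
                  dt = dt, record_stride = record_stride,
                  burst_time = burst_time, outcome = "running")
  outcome <- if (!is.na(burst_time)) "burst" else {
    ss <- steady_state_summary(tc, window = steady_window, tol = steady_tol)
    if (ss$dL_dt < 0.01 * params$dLdt_ref) "arrest"   # pressures may still
    else if (ss$steady) "steady"                      # accumulate in arrest
    else "unstable"
  }
  attr(tc, "outcome") <- outcome
  tc
}

#' Trailing-window steady-state summary
#'
#' Means of the growth rate, pressure differences, wall thickness and
#' extrusion rate over the trailing `window` seconds, with a steadiness flag
#' set when the relative drift (difference between the means of the two
#' half-windows, relative to the full-window mean) of every quantity is
#' below `tol`.
#'
#' @param tc A `tip_timecourse`.
#' @param window Trailing window, s.
#' @param tol Relative drift tolerance.
#' @return A list with `dL_dt`, `dPi`, `dP`, `L_wall`, `dVwall_dt`, `steady`.
#' @export
steady_state_summary <- function(tc, window = 100, tol = 1e-3) {
  stopifnot(inherits(tc, "tip_timecourse"))
  if (!is.na(attr(tc, "burst_time")))
    stop("burst trajectory has no steady state", call. = FALSE)
  tmax <- tc$t[nrow(tc)]
  if (tmax <= window)
    stop("trajectory shorter than the steady-state window", call. = FALSE)
  idx <- which(tc$t > tmax - window)
  if (length(idx) < 4)
    stop("too few samples in the steady-state window", call. = FALSE)
  vars <- c("dL_dt", "dPi", "dP", "L_wall", "dVwall_dt")
  half <- idx[seq_len(floor(length(idx) / 2))]
  rest <- setdiff(idx, half)
  drifts <- vapply(vars, function(v) {
    m <- mean(tc[[v]][idx])
    scale <- max(abs(m), 1e-12)
    abs(mean(tc[[v]][rest]) - mean(tc[[v]][half])) / scale
  }, numeric(1))
  out <- lapply(vars, function(v) mean(tc[[v]][idx]))
  names(out) <- vars
  out$steady <- all(drifts < tol)
  out$drifts <- drifts
  out
}

#' @export
print.tip_timecourse <- function(x, ...) {
  cat(sprintf("Tip-growth time course: %d samples over %.4g s, outcome '%s'\n",
              nrow(x), x$t[nrow(x)], attr(x, "outcome")))
  if (!is.na(attr(x, "burst_time")))
    cat(sprintf("  tip burst at t = %.4g s\n", attr(x, "burst_time")))
  utils::str(utils::head(as.data.frame(x), 3), give.attr = FALSE)
  invisible(x)
}

#' @export
summary.tip_timecourse <- function(object, window = 100, ...) {
  out <- attr(object, "outcome")
  cat("Outcome:", out, "\n")
  if (out != "burst") {
    ss <- steady_state_summary(object, window = window)
    cat(sprintf("Trailing %g s means: growth %.3g um/min, dPi %.3g MPa, dP %.3g MPa, L_wall %.3g um\n",
                window, ss$dL_dt * 60, ss$dPi, ss$dP, ss$L_wall))
    invisible(ss)
  } else {
    cat(sprintf("Burst at t = %.4g s\n", attr(object, "burst_time")))
    invisible(NULL)
  }
}

#' Initial state on the growing manifold
#'
#' Like [new_state()], but with the tip expansion throughput already
#' balancing baseline extrusion (steady film turnover) and the turgor and
#' sensor output consistent with it. Appropriate for scenarios that ask how
#' an already-growing cell behaves (e.g. whole-tube permeability), where the
#' stationary start would itself be a perturbation.
#'
#' @param params A [tip_params()] object.
#' @param sensor A calibrated [sensor_spec()].
#' @param G Osmotic conductance at start, um^3 MPa^-1 s^-1 (whole-tube runs
#'   pass `P_os_bar * 2*pi*r*L_init`).
#' @return A `tip_state`.
#' @export
growing_state <- function(params, sensor = no_sensor(), G = params$G_ref) {
  st <- new_state(params, sensor)
  E0 <- params$dVwall_baseline / params$L_wall_target
  st$E_smooth <- E0
  st$dP_smooth <- params$dPi_init - params$r * E0 / (2 * G)
  if (sensor$input != "none" && sensor$output == "wall_extrusion") {
    sensor <- calibrate_gain(sensor, params)
    st$ctrl_smooth <- sensor_output(sensor, params$dPi_init, st$dP_smooth,
                                    params$dVwall_baseline, G / params$G_ref)
  }
  st
}
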