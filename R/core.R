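## Instantaneous rate laws of the osmotic tip-growth model. All pure
## functions in um / s / MPa / osmol units; consumed by the integrator.

#' Osmotic water influx
#'
#' Rate of intracellular volume increase driven by the water potential
#' difference across the osmotically active membrane:
#' \eqn{dV/dt = P_{os} A_{mem} (\Delta\Pi - \Delta P)}. Negative values mean
#' efflux (plasmolysis).
#'
#' @param P_os_bar Osmotic permeability, um MPa^-1 s^-1.
#' @param A_mem Osmotically active membrane area, um^2.
#' @param dPi Osmotic pressure difference internal minus external, MPa.
#' @param dP Turgor pressure difference, MPa.
#' @return Volume influx in um^3/s.
#' @export
water_influx_rate <- function(P_os_bar, A_mem, dPi, dP) {
  stopifnot(P_os_bar > 0, A_mem > 0)
  P_os_bar * A_mem * (dPi - dP)
}

#' Linear growth rate from volume influx
#'
#' Cylinder geometry: \eqn{dL/dt = (dV/dt)/(\pi r^2)}.
#'
#' @param dV_dt Volume rate, um^3/s.
#' @param r Tube radius, um.
#' @return Linear growth rate, um/s.
#' @export
length_rate_from_volume <- function(dV_dt, r) {
  if (r <= 0) stop("tube radius must be positive", call. = FALSE)
  dV_dt / (pi * r^2)
}

#' Rate of change of internal osmotic pressure
#'
#' Time derivative of \eqn{\Pi_i = RT m / V}: solute accumulation minus
#' dilution by water entry, \eqn{(RT\, dm/dt - \Pi_i\, dV/dt)/V}.
#'
#' @param dm_dt Solute accumulation rate, osmol/s.
#' @param Pi_i Internal osmotic pressure, MPa.
#' @param dV_dt Volume influx, um^3/s.
#' @param V Cell volume, um^3.
#' @param temperature Absolute temperature, K.
#' @return Pressure rate, MPa/s.
#' @export
osmotic_pressure_rate <- function(dm_dt, Pi_i, dV_dt, V,
                                  temperature = 298.15) {
  if (V <= 0) stop("volume must be positive", call. = FALSE)
  (rt_um3(temperature) * dm_dt - Pi_i * dV_dt) / V
}

#' Net stretching tension on the apical film
#'
#' Young-Laplace tangential tension from turgor minus the film tension
#' opposing stretch, clamped at zero: \eqn{T = \max(0, \Delta P\, r/2 - \gamma)}.
#' The clamp encodes that the film is only ever stretched, never actively
#' contracted.
#'
#' @param dP Turgor pressure, MPa.
#' @param r Radius of curvature, um.
#' @param gamma Film tension, MPa um.
#' @return Tension, MPa um.
#' @export
tip_tension <- function(dP, r, gamma) {
  stopifnot(r > 0, gamma >= 0)
  pmax(0, dP * r / 2 - gamma)
}

#' Apical film viscosity with hardening
#'
#' Initial pectin viscosity plus an incremental term equal to the hardening
#' rate times the mean residence time of material in the film,
#' \eqn{\eta = \eta_0 + \alpha\, A_{tip} L_{wall} / (dV_{wall}/dt)}. When
#' extrusion is zero the film is fully hardened and a large cap
#' (`cap` x `eta_0`) is returned.
#'
#' @param eta_0 Initial viscosity, MPa s.
#' @param alpha Hardening rate (viscosity gain per unit residence time).
#' @param dVwall_dt Pectin extrusion rate, um^3/s.
#' @param A_tip Apical disc area, um^2.
#' @param L_wall Film thickness, um.
#' @param cap Cap multiple of `eta_0` for zero extrusion.
#' @return Viscosity, MPa s.
#' @export
wall_viscosity <- function(eta_0, alpha, dVwall_dt, A_tip, L_wall,
                           cap = 1e6) {
  stopifnot(eta_0 > 0, alpha >= 0, dVwall_dt >= 0, A_tip > 0, L_wall >= 0)
  cap_val <- cap * eta_0
  if (dVwall_dt <= 0) return(cap_val)
  min(cap_val, eta_0 + alpha * A_tip * L_wall / dVwall_dt)
}

#' Tip area expansion throughput
#'
#' Strain-rate law of the stretched viscous disc,
#' \eqn{(dA_{tip}/dt)/A_{tip} = T/(\eta L_{wall})}. The disc area itself is
#' held constant; `E` is the area throughput exported from the disc to the
#' shank wall, so the linear growth rate is \eqn{E/(2\pi r)}.
#'
#' @param tension Net tension, MPa um.
#' @param eta Film viscosity, MPa s.
#' @param L_wall Film thickness, um.
#' @param A_tip Disc area, um^2.
#' @return Area throughput, um^2/s (non-negative).
#' @export
tip_expansion_rate <- function(tension, eta, L_wall, A_tip) {
  stopifnot(eta > 0, A_tip > 0)
  if (L_wall <= 0)
    stop("wall thickness must be positive (burst upstream)", call. = FALSE)
  max(0, A_tip * tension / (eta * L_wall))
}

#' Wall thickening rate
#'
#' Volume conservation in the apical film: extrusion in, stretched film out,
#' \eqn{dL_{wall}/dt = (dV_{wall}/dt - L_{wall} E)/A_{tip}}.
#'
#' @param dVwall_dt Extrusion rate, um^3/s.
#' @param E Area throughput, um^2/s.
#' @param A_tip Disc area, um^2.
#' @param L_wall Film thickness, um.
#' @return Thickness rate, um/s.
#' @export
wall_thickness_rate <- function(dVwall_dt, E, A_tip, L_wall) {
  stopifnot(A_tip > 0)
  (dVwall_dt - L_wall * E) / A_tip
}

## Piecewise-linear turgor balance, scalar core. Solves
##   G (dPi - dP) = r A_tip max(0, dP r/2 - gamma) / (2 eta L_wall)
## i.e. water influx equals the volume accommodated by tip expansion
## (incompressible cytoplasm, instantaneous mechanical equilibrium).
solve_turgor_core <- function(dPi, G, r, A_tip, eta, L_wall, gamma) {
  stopifnot(G > 0, r > 0, A_tip > 0, eta > 0, L_wall > 0, gamma >= 0)
  dP_clamp <- if (r > 0) 2 * gamma / r else 0
  if (dPi <= dP_clamp) {
    # tension clamp active: no expansion, no influx; water equilibrium
    return(max(0, dPi))
  }
  C <- r * A_tip / (2 * eta * L_wall)      # volume rate per unit tension
  dP <- (G * dPi + C * gamma) / (G + C * r / 2)
  if (dP * r / 2 < gamma) dP <- dPi        # consistency fallback
  if (dP < 0 || dP > dPi)
    stop("turgor balance has no solution in [0, dPi]", call. = FALSE)
  dP
}

#' Solve the quasi-static turgor balance
#'
#' Turgor is not a state variable: the cytoplasm is treated as incompressible,
#' so at each instant \eqn{\Delta P} solves the linear balance between osmotic
#' water influx and the volume created by viscous tip expansion,
#' \deqn{P_{os} A_{mem} (\Delta\Pi - \Delta P) =
#'       r A_{tip} \max(0, \Delta P r/2 - \gamma) / (2 \eta L_{wall}).}
#' In the rigid-wall limit (\eqn{\eta L_{wall} \to \infty}) this gives
#' \eqn{\Delta P \to \Delta\Pi}; when the tension clamp is active the cell sits
#' at water equilibrium.
#'
#' @param state A model state as produced by [new_state()] (uses `Pi_i`,
#'   `L_wall` and the smoothed extrusion rate for the viscosity).
#' @param params A [tip_params()] object (effective values at the current
#'   time).
#' @return Turgor pressure difference \eqn{\Delta P}, MPa.
#' @export
solve_turgor <- function(state, params) {
  if (isTRUE(state$burst)) stop("cannot solve turgor for a burst state",
                                call. = FALSE)
  Pi_o <- vant_hoff_pressure(params$C_o, params$temperature)
  dPi <- state$Pi_i - Pi_o
  eta <- wall_viscosity(params$eta_0, params$alpha, state$dVwall_smooth,
                        params$A_tip, state$L_wall, params$eta_cap_factor)
  solve_turgor_core(dPi, params$P_os_bar * params$A_mem, params$r,
                    params$A_tip, eta, state$L_wall, params$gamma)
}
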