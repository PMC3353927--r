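#' Model parameters for the tip-growth simulator
#'
#' Builds the full, internally consistent parameter set of the osmotic
#' tip-growth model in the canonical um / s / MPa / osmol unit system.
#' Geometry, permeability and medium composition default to the standard
#' *Lilium longiflorum* values (tube radius 8 um, apical osmotic zone of
#' 20 um, permeability 9.36e-6 cm MPa^-1 s^-1, medium 0.3 Osm). The
#' mechanical and supply constants that the literature does not print
#' (sensor gain `K`, hardening rate `alpha`, solute accumulation `dm_dt`,
#' baseline wall extrusion `dVwall_baseline`) are calibrated algebraically
#' from the steady-state balance so that the unperturbed model grows at the
#' observed rate (~12 um/min) with the observed wall thickness
#' (`L_wall_target`, default 0.25 um) and the observed pressure set point
#' (`dPi_target` = 0.86 MPa, `dP_target` = 0.43 MPa, i.e. turgor about half
#' the osmotic gradient and a water-potential discrepancy of 0.43 MPa).
#'
#' The calibration closure is:
#' \itemize{
#'  \item conductance \eqn{G = P_{os} A_{mem}}, influx
#'        \eqn{dV/dt = G(\Delta\Pi - \Delta P)};
#'  \item tip area throughput \eqn{E = 2 dV/dt / r}, extrusion
#'        \eqn{dV_{wall}/dt = L_{wall} E}, sensor gain
#'        \eqn{K = (dV_{wall}/dt)/(\Delta\Pi-\Delta P)};
#'  \item film viscosity from the expansion law
#'        \eqn{\eta = A_{tip} T / (E L_{wall})} with
#'        \eqn{T = \Delta P r/2 - \gamma}, split into `eta_0` plus the
#'        hardening term, which fixes `alpha`;
#'  \item solute supply from the dilution balance
#'        \eqn{RT\, dm/dt = \Pi_i\, dV/dt}.
#' }
#'
#' @param r Tube radius, um (also the tip radius of curvature).
#' @param r_tip Apical extrusion-disc radius, um.
#' @param A_tip Apical disc area, um^2; by default the spherical-cap area
#'   implied by `r` and `r_tip`.
#' @param L_perm Length of the osmotically permeable apical zone, um.
#' @param A_mem Osmotically active membrane area, um^2; must equal
#'   `2*pi*r*L_perm` when `L_perm` is given.
#' @param P_os_bar Osmotic permeability in pressure form, um MPa^-1 s^-1.
#' @param P_os_cm Same permeability in concentration form, cm/s; derived from
#'   `P_os_bar` when omitted, checked for van 't Hoff consistency (5%) when
#'   both are supplied.
#' @param C_o External osmolarity, Osm.
#' @param C_Ca External calcium concentration, mM (used by the hardening law).
#' @param temperature Absolute temperature, K.
#' @param dt Integration step, s.
#' @param burst_threshold Wall thickness below which the tip bursts, um.
#' @param gamma Film tension opposing stretch, MPa um.
#' @param eta_0 Initial (unhardened) pectin viscosity, MPa s.
#' @param L_wall_target Calibration target for steady wall thickness, um.
#' @param dPi_target,dP_target Calibration targets for the steady osmotic and
#'   turgor pressure differences, MPa.
#' @param alpha Hardening rate (viscosity gain per unit film residence time,
#'   MPa s per s); calibrated when `NULL`.
#' @param K Sensor gain at the reference membrane area, um^3 MPa^-1 s^-1;
#'   calibrated when `NULL`.
#' @param dm_dt Solute accumulation rate, osmol/s; calibrated when `NULL`.
#' @param dVwall_baseline Sensor-independent wall extrusion rate, um^3/s;
#'   calibrated when `NULL`.
#' @param dPi_init Initial osmotic gradient of the solute-loaded stationary
#'   tube, MPa; defaults to `dPi_target`.
#' @param L_init Initial tube length, um.
#' @param ht_expansion Smoothing half-time applied to the tip expansion rate,
#'   s (default half the time step).
#' @param ht_turgor Relaxation half-time of the mechanically acting turgor
#'   toward the quasi-static balance, s (default half the time step). This
#'   short lag is what lets the thin-film instability (and hence bursting)
#'   exist at all; the instantaneous balance would cap expansion at the water
#'   supply and make the film unconditionally stable.
#' @param ht_sensor Response half-time of the sensor signalling chain, s.
#' @param ht_param Smoothing half-time applied to step parameter changes, s.
#' @param eta_cap_factor Multiple of `eta_0` used as the viscosity cap when
#'   extrusion is zero (fully hardened film).
#' @return An object of class `tip_params`: a named list of parameters plus
#'   derived reference quantities (`A_mem_ref`, conductance `G_ref`, reference
#'   growth rate `dLdt_ref`).
#' @examples
#' p <- tip_params()
#' p$K       # ~5.9 um^3 MPa^-1 s^-1
#' p$dLdt_ref * 60  # ~12 um/min
#' @export
tip_params <- function(r = 8, r_tip = 2, A_tip = NULL,
                       L_perm = 20, A_mem = NULL,
                       P_os_bar = 0.0936, P_os_cm = NULL,
                       C_o = 0.3, C_Ca = 0.1,
                       temperature = 298.15,
                       dt = 0.4, burst_threshold = 2e-4,
                       gamma = 0.12, eta_0 = 0.3,
                       L_wall_target = 0.25,
                       dPi_target = 0.86, dP_target = 0.43,
                       alpha = NULL, K = NULL, dm_dt = NULL,
                       dVwall_baseline = NULL,
                       dPi_init = NULL, L_init = 500,
                       ht_expansion = dt / 2, ht_turgor = dt,
                       ht_sensor = dt, ht_param = dt / 2,
                       eta_cap_factor = 1e6) {
  stopifnot(r > 0, r_tip > 0, L_perm > 0, P_os_bar > 0, C_o >= 0,
            temperature > 0, dt > 0, burst_threshold > 0,
            gamma >= 0, eta_0 > 0, L_wall_target > 0,
            dPi_target > dP_target, dP_target > 0, L_init > 0,
            ht_expansion > 0, ht_turgor > 0, ht_sensor > 0, ht_param > 0)
  if (r_tip > r) stop("r_tip cannot exceed the tube radius r", call. = FALSE)

  if (is.null(A_tip)) {
    # spherical cap of chord radius r_tip on a sphere of radius r
    A_tip <- 2 * pi * r * (r - sqrt(r^2 - r_tip^2))
  }
  stopifnot(A_tip > 0)

  if (is.null(A_mem)) {
    A_mem <- 2 * pi * r * L_perm
  } else if (abs(A_mem - 2 * pi * r * L_perm) > 1e-6 * A_mem) {
    stop("A_mem must equal 2*pi*r*L_perm (", signif(2 * pi * r * L_perm, 6),
         " um^2) when L_perm is given", call. = FALSE)
  }

  if (is.null(P_os_cm)) {
    P_os_cm <- pos_bar_to_cm(P_os_bar, temperature)
  } else {
    implied <- pos_cm_to_bar(P_os_cm, temperature)
    if (abs(implied - P_os_bar) > 0.05 * P_os_bar)
      stop("P_os_cm and P_os_bar disagree by more than 5% under the ",
           "van 't Hoff conversion", call. = FALSE)
  }

  ## ---- steady-state calibration at the target operating point ----
  G <- P_os_bar * A_mem                      # um^3 MPa^-1 s^-1
  wp <- dPi_target - dP_target               # water potential discrepancy
  dV <- G * wp                               # influx, um^3/s
  dLdt <- dV / (pi * r^2)                    # um/s
  E <- 2 * dV / r                            # tip area throughput, um^2/s
  dVwall <- L_wall_target * E                # extrusion at steady state
  tension <- dP_target * r / 2 - gamma
  if (tension <= 0)
    stop("gamma too large: no positive tension at the calibration point",
         call. = FALSE)
  eta_star <- A_tip * tension / (E * L_wall_target)
  if (eta_star <= eta_0)
    stop("eta_0 exceeds the calibrated operating viscosity", call. = FALSE)

  if (is.null(K)) K <- dVwall / wp
  if (is.null(alpha))
    alpha <- (eta_star - eta_0) * dVwall / (A_tip * L_wall_target)
  if (is.null(dVwall_baseline)) dVwall_baseline <- dVwall
  Pi_o <- vant_hoff_pressure(C_o, temperature)
  if (is.null(dm_dt)) dm_dt <- (Pi_o + dPi_target) * dV / rt_um3(temperature)
  if (is.null(dPi_init)) dPi_init <- dPi_target
  stopifnot(alpha >= 0, K >= 0, dm_dt > 0, dVwall_baseline > 0)

  p <- list(r = r, r_tip = r_tip, A_tip = A_tip,
            L_perm = L_perm, A_mem = A_mem,
            P_os_bar = P_os_bar, P_os_cm = P_os_cm,
            C_o = C_o, C_Ca = C_Ca, temperature = temperature,
            dt = dt, burst_threshold = burst_threshold,
            gamma = gamma, eta_0 = eta_0,
            alpha = alpha, K = K, dm_dt = dm_dt,
            dVwall_baseline = dVwall_baseline,
            L_wall_target = L_wall_target,
            dPi_target = dPi_target, dP_target = dP_target,
            dPi_init = dPi_init, L_init = L_init,
            ht_expansion = ht_expansion, ht_turgor = ht_turgor,
            ht_sensor = ht_sensor, ht_param = ht_param,
            eta_cap_factor = eta_cap_factor,
            A_mem_ref = A_mem, G_ref = G, dLdt_ref = dLdt)
  class(p) <- "tip_params"
  p
}

#' @export
print.tip_params <- function(x, ...) {
  cat("Tip-growth model parameters (um / s / MPa / osmol)\n")
  cat(sprintf("  geometry:  r = %g um, r_tip = %g um, A_tip = %.3g um^2\n",
              x$r, x$r_tip, x$A_tip))
  cat(sprintf("  osmotic:   L_perm = %g um, A_mem = %.4g um^2, P_os = %g um/(MPa s) (%.3g cm/s)\n",
              x$L_perm, x$A_mem, x$P_os_bar, x$P_os_cm))
  cat(sprintf("  medium:    C_o = %g Osm, C_Ca = %g mM, T = %g K\n",
              x$C_o, x$C_Ca, x$temperature))
  cat(sprintf("  wall:      eta_0 = %g MPa s, alpha = %.4g, gamma = %g MPa um\n",
              x$eta_0, x$alpha, x$gamma))
  cat(sprintf("  supply:    dm/dt = %.4g osmol/s, dVwall = %.4g um^3/s, K = %.4g um^3/(MPa s)\n",
              x$dm_dt, x$dVwall_baseline, x$K))
  cat(sprintf("  reference: growth %.3g um/min, dPi* = %g, dP* = %g, L_wall* = %g um\n",
              x$dLdt_ref * 60, x$dPi_target, x$dP_target, x$L_wall_target))
  invisible(x)
}

#' Modify a parameter set
#'
#' Returns a copy of `params` with the named fields replaced. Derived fields
#' (`A_mem`, `A_mem_ref`, `G_ref`) are recomputed when geometry or
#' permeability change; calibrated constants are kept as-is.
#'
#' @param params A `tip_params` object.
#' @param ... Named replacement values.
#' @export
modify_params <- function(params, ...) {
  stopifnot(inherits(params, "tip_params"))
  repl <- list(...)
  unknown <- setdiff(names(repl), names(params))
  if (length(unknown))
    stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (nm in names(repl)) params[[nm]] <- repl[[nm]]
  if (any(c("L_perm", "r", "P_os_bar") %in% names(repl))) {
    if (!"A_mem" %in% names(repl))
      params$A_mem <- 2 * pi * params$r * params$L_perm
  }
  params
}
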