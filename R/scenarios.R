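## Declarative perturbation schedules on named parameters.

PERTURBABLE <- c("C_o", "alpha", "L_perm", "dVwall_baseline", "P_os_bar")

#' Define a single perturbation
#'
#' A step moves a parameter from its base value to `value` at `onset`
#' (passed through exponential smoothing with the configured half-time, so
#' the transition is fast but not discontinuous). A sinusoid modulates the
#' parameter multiplicatively,
#' `base * (1 + amplitude * sin(2*pi*frequency*(t - onset)/60 + phase))`.
#'
#' @param parameter One of `"C_o"`, `"alpha"`, `"L_perm"`,
#'   `"dVwall_baseline"`, `"P_os_bar"`.
#' @param shape `"step"` or `"sinusoid"`.
#' @param onset Onset time, s.
#' @param value New value after a step (same units as the parameter).
#' @param amplitude Relative sinusoid amplitude (must be < 1 so the
#'   parameter stays positive).
#' @param frequency Sinusoid frequency, cycles per minute.
#' @param phase Sinusoid phase, radians.
#' @param half_time Smoothing half-time for a step transition, s; `NULL`
#'   uses the parameter set's `ht_param`. Hardening (calcium) steps use a
#'   longer default (10 s) because external calcium equilibrates with the
#'   wall over seconds rather than instantaneously.
#' @return A `perturbation` object.
#' @export
perturbation <- function(parameter, shape = c("step", "sinusoid"),
                         onset = 0, value = NULL,
                         amplitude = 0.5, frequency = 1.2, phase = 0,
                         half_time = if (parameter == "alpha") 10 else NULL) {
  if (!parameter %in% PERTURBABLE)
    stop("unknown perturbable parameter '", parameter, "'; must be one of: ",
         paste(PERTURBABLE, collapse = ", "), call. = FALSE)
  shape <- match.arg(shape)
  stopifnot(onset >= 0)
  if (shape == "step") {
    if (is.null(value) || value < 0)
      stop("a step perturbation needs a non-negative 'value'", call. = FALSE)
  } else {
    stopifnot(amplitude > 0, amplitude < 1, frequency > 0)
  }
  if (!is.null(half_time)) stopifnot(half_time > 0)
  structure(list(parameter = parameter, shape = shape, onset = onset,
                 value = value, amplitude = amplitude,
                 frequency = frequency, phase = phase,
                 half_time = half_time),
            class = "perturbation")
}

#' Assemble a perturbation scenario
#'
#' @param ... [perturbation()] objects (possibly none, for the unperturbed
#'   baseline).
#' @param A_mem_mode `"osmotic_zone"` keeps the osmotically active area tied
#'   to the fixed apical zone (`2*pi*r*L_perm`); `"whole_tube"` halts the
#'   impermeabilization that normally trails the tip, so every piece of
#'   membrane laid down after the start stays water-permeable and the
#'   osmotic area grows with the surface expansion of the cell,
#'   `A_mem = 2*pi*r*(L_perm + L - L_init)`.
#' @param dm_mode `"fixed"` keeps the solute accumulation rate constant (the
#'   standard model); `"per_area"` scales it with the osmotically active
#'   membrane area relative to its reference value, so that solute uptake
#'   (a membrane-transport process) keeps pace with the permeable area.
#'   Used by the whole-tube-permeability scenarios, where growth would
#'   otherwise be throttled by the fixed supply rather than by membrane
#'   area; it pins the operating pressures while growth scales with area.
#' @param name Optional scenario name.
#' @return A `scenario` object.
#' @export
scenario <- function(..., A_mem_mode = c("osmotic_zone", "whole_tube"),
                     dm_mode = c("fixed", "per_area"),
                     name = NULL) {
  perts <- list(...)
  if (length(perts) == 1 && is.list(perts[[1]]) &&
      !inherits(perts[[1]], "perturbation"))
    perts <- perts[[1]]
  ok <- vapply(perts, inherits, logical(1), "perturbation")
  if (!all(ok)) stop("all perturbations must be perturbation objects",
                     call. = FALSE)
  structure(list(perturbations = perts,
                 A_mem_mode = match.arg(A_mem_mode),
                 dm_mode = match.arg(dm_mode),
                 name = name),
            class = "scenario")
}

#' @export
print.scenario <- function(x, ...) {
  cat("Scenario", if (!is.null(x$name)) paste0("'", x$name, "'"), "\n")
  cat("  A_mem mode:", x$A_mem_mode, "\n")
  if (!length(x$perturbations)) cat("  (unperturbed baseline)\n")
  for (p in x$perturbations) {
    if (p$shape == "step")
      cat(sprintf("  step  %s -> %g at t = %g s\n", p$parameter, p$value,
                  p$onset))
    else
      cat(sprintf("  sine  %s, amplitude %g, %g min^-1, from t = %g s\n",
                  p$parameter, p$amplitude, p$frequency, p$onset))
  }
  invisible(x)
}

## smoothed step transition (closed form of repeated exp_relax)
step_value <- function(base, value, t, onset, half_time) {
  if (t < onset) return(base)
  base + (value - base) * (1 - 2^(-(t - onset) / half_time))
}

#' Effective parameters at a given time under a scenario
#'
#' Applies every scheduled perturbation to the base parameter set at time
#' `t`. Step changes are smoothed exponentially with the parameter
#' half-time; sinusoids are applied directly. `A_mem` is recomputed from
#' `L_perm` whenever `L_perm` is driven (or from the current tube length `L`
#' in whole-tube mode).
#'
#' @param base A [tip_params()] object.
#' @param scen A [scenario()] or `NULL` for no perturbation.
#' @param t Time, s.
#' @param L Current tube length, um (used only in whole-tube mode).
#' @return A `tip_params` object with effective values.
#' @export
effective_params <- function(base, scen, t, L = base$L_init) {
  p <- base
  if (!is.null(scen)) {
    for (pert in scen$perturbations) {
      if (t < pert$onset) next
      b <- base[[pert$parameter]]
      p[[pert$parameter]] <-
        if (pert$shape == "step") {
          ht <- if (is.null(pert$half_time)) base$ht_param else pert$half_time
          step_value(b, pert$value, t, pert$onset, ht)
        } else {
          b * (1 + pert$amplitude *
                 sin(2 * pi * pert$frequency * (t - pert$onset) / 60 +
                       pert$phase))
        }
    }
  }
  if (!is.null(scen) && scen$A_mem_mode == "whole_tube") {
    p$A_mem <- 2 * pi * p$r * (p$L_perm + max(0, L - base$L_init))
  } else {
    p$A_mem <- 2 * pi * p$r * p$L_perm
  }
  p
}

## ---- presets reproducing the simulation figures -------------------------

PRESET_ONSET <- 500

preset_table <- function() {
  list(
    fig3_alpha_zero = list(
      desc = "hardening abolished (external calcium removed): tip bursts",
      sensor = TRUE,
      build = function(p) scenario(perturbation("alpha", "step",
                                                onset = PRESET_ONSET,
                                                value = 0),
                                   name = "fig3_alpha_zero")),
    fig3_alpha_x20 = list(
      desc = "hardening x20 (calcium 0.1 -> 2 mM): growth arrest",
      sensor = TRUE,
      build = function(p) scenario(perturbation("alpha", "step",
                                                onset = PRESET_ONSET,
                                                value = 20 * p$alpha),
                                   name = "fig3_alpha_x20")),
    fig3_alpha_half = list(
      desc = "hardening halved: turgor falls, growth rises, wall stable",
      sensor = TRUE,
      build = function(p) scenario(perturbation("alpha", "step",
                                                onset = PRESET_ONSET,
                                                value = 0.5 * p$alpha),
                                   name = "fig3_alpha_half")),
    fig5_dilute = list(
      desc = "medium diluted 0.3 -> 0.2 Osm: faster growth, stable wall",
      sensor = TRUE,
      build = function(p) scenario(perturbation("C_o", "step",
                                                onset = PRESET_ONSET,
                                                value = 0.2),
                                   name = "fig5_dilute")),
    fig5_shock = list(
      desc = "hypotonic shock 0.3 -> 0.01 Osm: bursting",
      sensor = TRUE,
      build = function(p) scenario(perturbation("C_o", "step",
                                                onset = PRESET_ONSET,
                                                value = 0.01),
                                   name = "fig5_shock")),
    fig5_hyper = list(
      desc = "medium raised 0.3 -> 0.4 Osm: slower growth, stable wall",
      sensor = TRUE,
      build = function(p) scenario(perturbation("C_o", "step",
                                                onset = PRESET_ONSET,
                                                value = 0.4),
                                   name = "fig5_hyper")),
    fig6_whole_tube_permeable = list(
      desc = "whole tube osmotically permeable, sensor on: accelerating growth",
      sensor = TRUE,
      build = function(p) scenario(A_mem_mode = "whole_tube",
                                   dm_mode = "per_area",
                                   name = "fig6_whole_tube_permeable")),
    fig6_whole_tube_no_sensor = list(
      desc = "whole tube permeable, no sensor: wall thins continually",
      sensor = FALSE,
      build = function(p) scenario(A_mem_mode = "whole_tube",
                                   dm_mode = "per_area",
                                   name = "fig6_whole_tube_no_sensor")),
    fig10_pectin_sine = list(
      desc = "pectin extrusion driven sinusoidally, no sensor",
      sensor = FALSE,
      build = function(p) scenario(perturbation("dVwall_baseline", "sinusoid",
                                                onset = PRESET_ONSET,
                                                amplitude = 0.5,
                                                frequency = 1.2),
                                   name = "fig10_pectin_sine")),
    fig10_alpha_sine = list(
      desc = "hardening rate driven sinusoidally, no sensor",
      sensor = FALSE,
      build = function(p) scenario(perturbation("alpha", "sinusoid",
                                                onset = PRESET_ONSET,
                                                amplitude = 0.5,
                                                frequency = 1.2),
                                   name = "fig10_alpha_sine")),
    fig11_Lperm_sine = list(
      desc = "osmotic-zone length driven sinusoidally, sensor on",
      sensor = TRUE,
      build = function(p) scenario(perturbation("L_perm", "sinusoid",
                                                onset = PRESET_ONSET,
                                                amplitude = 1 / 3,
                                                frequency = 1.2),
                                   name = "fig11_Lperm_sine")),
    fig11_Lperm_sine_no_sensor = list(
      desc = "osmotic-zone length driven sinusoidally, no sensor",
      sensor = FALSE,
      build = function(p) scenario(perturbation("L_perm", "sinusoid",
                                                onset = PRESET_ONSET,
                                                amplitude = 1 / 3,
                                                frequency = 1.2),
                                   name = "fig11_Lperm_sine_no_sensor"))
  )
}

#' Named preset scenarios
#'
#' Scenarios reproducing the simulation regimes: the hardening battery
#' (calcium removal, 20x calcium, halved hardening), the external-osmolarity
#' battery (dilution, hypotonic shock, hypertonic medium), whole-tube
#' permeability with and without sensor, and the sinusoidal drives of pectin
#' extrusion, hardening, and osmotic-zone length.
#'
#' @param name Preset name; see [preset_names()].
#' @param params Parameter set used to resolve relative perturbations
#'   (e.g. `alpha` multiples).
#' @return A list with elements `scenario` (a [scenario()]), `sensor`
#'   (`TRUE` for the water-potential osmosensor, `FALSE` for none) and
#'   `desc`.
#' @export
preset_scenario <- function(name, params = tip_params()) {
  tab <- preset_table()
  if (!name %in% names(tab))
    stop("unknown preset '", name, "'; see preset_names()", call. = FALSE)
  entry <- tab[[name]]
  list(scenario = entry$build(params),
       sensor = entry$sensor,
       desc = entry$desc)
}

#' @rdname preset_scenario
#' @export
preset_names <- function() names(preset_table())

#' Quasi-steady osmotic gradient for a given conductance
#'
#' Solves the operating osmotic gradient at which mechanical expansion and
#' solute dilution balance for an osmotic conductance `G` (by default the
#' whole-tube conductance at the initial length). Used to initialize
#' whole-tube-permeability runs at their own operating point rather than at
#' the apical-zone loading, which would amount to an osmotic shock.
#'
#' @param params A [tip_params()] object.
#' @param G Osmotic conductance `P_os * A_mem`, um^3 MPa^-1 s^-1; defaults
#'   to the whole-tube value at `L_init`.
#' @return The quasi-steady osmotic gradient, MPa.
#' @export
equilibrium_dPi <- function(params,
                            G = params$P_os_bar * 2 * pi * params$r *
                              params$L_init) {
  p <- params
  Lw <- p$K * p$r / (2 * p$G_ref)   # sensor-held wall thickness
  Pi_o <- vant_hoff_pressure(p$C_o, p$temperature)
  hard <- 2 * p$alpha * p$A_tip * Lw^2 * p$G_ref / (p$r * p$K)
  u_mech <- function(dPi) {
    num <- p$A_tip * (dPi * p$r / 2 - p$gamma) - hard
    den <- 2 * G * p$eta_0 * Lw / p$r + p$A_tip * p$r / 2
    max(0, num / den)
  }
  f <- function(dPi)
    G * u_mech(dPi) - rt_um3(p$temperature) * p$dm_dt / (Pi_o + dPi)
  lo <- (2 / p$r) * (p$gamma + hard / p$A_tip) + 1e-6
  stats::uniroot(f, c(lo, 10), tol = 1e-10)$root
}
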