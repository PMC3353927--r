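## Stability screen over candidate sensor couplings: which sensed signal,
## controlling which rate, keeps growth, wall thickness and turgor stable
## under the experimentally accessible perturbations.

#' Classify the response of a perturbed run
#'
#' Compares the trailing window of a perturbed trajectory against the
#' pre-perturbation steady values. A quantity "changes" when its maximum
#' deviation from the pre-perturbation mean over the trailing window exceeds
#' the relative threshold (default 10%), which catches both sustained steps
#' and sustained oscillations.
#'
#' @param tc A `tip_timecourse` from a perturbed run.
#' @param baseline_summary A [steady_state_summary()] of the
#'   pre-perturbation steady state (or of the pre-onset segment).
#' @param window Trailing window, s.
#' @param threshold Relative change threshold.
#' @return A list with `growth_changed`, `thickness_changed`,
#'   `turgor_changed`, and `outcome_label`.
#' @export
classify_outcome <- function(tc, baseline_summary, window = 100,
                             threshold = 0.1) {
  stopifnot(inherits(tc, "tip_timecourse"))
  if (!isTRUE(baseline_summary$steady))
    stop("no pre-perturbation steady state to compare against",
         call. = FALSE)
  out <- attr(tc, "outcome")
  if (out == "burst") {
    return(list(growth_changed = TRUE, thickness_changed = TRUE,
                turgor_changed = TRUE, outcome_label = "burst"))
  }
  tmax <- tc$t[nrow(tc)]
  idx <- which(tc$t > tmax - window)
  changed <- function(var, base) {
    max(abs(tc[[var]][idx] - base)) / max(abs(base), 1e-12) > threshold
  }
  list(growth_changed = changed("dL_dt", baseline_summary$dL_dt),
       thickness_changed = changed("L_wall", baseline_summary$L_wall),
       turgor_changed = changed("dP", baseline_summary$dP),
       outcome_label = out)
}

## default perturbation battery: the two experimentally accessible handles
## (external osmolarity, hardening via calcium) stepped by >= 50% of their
## steady values, plus the osmotic-zone oscillation.
screen_perturbations <- function(params, onset = 500) {
  list(
    Pi_o = scenario(perturbation("C_o", "step", onset = onset,
                                 value = 1.5 * params$C_o),
                    name = "Pi_o_step"),
    alpha = scenario(perturbation("alpha", "step", onset = onset,
                                  value = 0.5 * params$alpha),
                     name = "alpha_step"),
    L_perm = scenario(perturbation("L_perm", "sinusoid", onset = onset,
                                   amplitude = 0.5, frequency = 1.2),
                      name = "L_perm_sine")
  )
}

#' Run the sensor-coupling stability screen
#'
#' For every candidate sensor coupling (all nine input-output pairs plus the
#' no-sensor control, or a supplied subset), first runs the unperturbed
#' model to ask whether the coupling admits steady growth at all, then
#' applies each perturbation and classifies whether growth rate, tip wall
#' thickness and turgor pressure change.
#'
#' @param params A [tip_params()] object.
#' @param perturbations Named list of [scenario()]s; defaults to steps of
#'   external osmolarity (x1.5) and hardening (x0.5, the published
#'   halved-hardening simulation) and the osmotic-zone sinusoid (50%), all
#'   at least 50% of the steady values.
#' @param specs Named list of [sensor_spec()]s; defaults to
#'   [enumerate_couplings()].
#' @param duration Run length, s (perturbations onset at 500 s).
#' @param settle_window,settle_tol Steadiness window and tolerance used both
#'   for the admits-steady-state check and the pre-onset baseline.
#' @param threshold Relative "changed" threshold for [classify_outcome()].
#' @return A data frame with one row per (sensor, perturbation): columns
#'   `sensor`, `input`, `output`, `admits_steady`, `perturbation`,
#'   `growth_changed`, `thickness_changed`, `turgor_changed`, `outcome`.
#'   Attribute `"unperturbed"` holds the per-sensor unperturbed outcomes.
#' @export
sensor_screen <- function(params = tip_params(),
                          perturbations = screen_perturbations(params),
                          specs = enumerate_couplings(params),
                          duration = 3000,
                          settle_window = 100, settle_tol = 2e-3,
                          threshold = 0.1) {
  stopifnot(length(names(specs)) == length(specs))
  rows <- list()
  unpert <- list()
  for (snm in names(specs)) {
    spec <- calibrate_gain(specs[[snm]], params)
    tc0 <- run(params, NULL, sensor = spec, duration = 1500,
               steady_window = settle_window, steady_tol = settle_tol)
    base <- if (attr(tc0, "outcome") == "burst") NULL
            else steady_state_summary(tc0, settle_window, settle_tol)
    admits <- !is.null(base) && isTRUE(base$steady) &&
      base$dL_dt > 0.01 * params$dLdt_ref
    unpert[[snm]] <- list(outcome = attr(tc0, "outcome"), admits = admits,
                          summary = base)
    for (pnm in names(perturbations)) {
      if (!admits) {
        rows[[length(rows) + 1L]] <-
          data.frame(sensor = snm, input = spec$input, output = spec$output,
                     admits_steady = FALSE, perturbation = pnm,
                     growth_changed = NA, thickness_changed = NA,
                     turgor_changed = NA, outcome = "no_steady_growth")
        next
      }
      tc <- run(params, perturbations[[pnm]], sensor = spec,
                duration = duration)
      cls <- classify_outcome(tc, base, threshold = threshold)
      rows[[length(rows) + 1L]] <-
        data.frame(sensor = snm, input = spec$input, output = spec$output,
                   admits_steady = TRUE, perturbation = pnm,
                   growth_changed = cls$growth_changed,
                   thickness_changed = cls$thickness_changed,
                   turgor_changed = cls$turgor_changed,
                   outcome = cls$outcome_label)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  attr(res, "unperturbed") <- unpert
  class(res) <- c("sensor_screen", "data.frame")
  res
}

#' @export
print.sensor_screen <- function(x, ...) {
  cat("Sensor-coupling stability screen\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Write a screen matrix as CSV
#'
#' @param x A [sensor_screen()] result.
#' @param path Output file.
#' @export
write_screen <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
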