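## Calcium-to-hardening law: the rate at which calcium cross-linking
## stiffens the freshly extruded pectin film.

#' Hardening law of the pectin tip gel
#'
#' Calcium diffuses into the demethylated pectin film and is fixed by
#' carboxyl binding sites; the resulting hardening rate is linear in the
#' external calcium concentration and scales with the square root of the
#' binding constant and of the diffusivity:
#' \deqn{\alpha = k_{scale}\, C_{Ca}\, \sqrt{K_c D}.}
#' The absolute prefactor is not known, so `k_scale` is calibrated such
#' that the baseline medium (0.1 mM calcium) reproduces the parameter
#' set's baseline hardening rate.
#'
#' @param K_c Calcium binding constant of the pectin gel, mM^-1.
#' @param D Calcium diffusivity in the wall, um^2/s.
#' @param k_scale Proportionality constant; `NULL` to calibrate against
#'   `params`.
#' @param params A [tip_params()] object used for calibration.
#' @return A `hardening_law` object.
#' @examples
#' law <- hardening_law()
#' alpha_from_calcium(law, 0.1)  # baseline alpha
#' alpha_from_calcium(law, 2) / alpha_from_calcium(law, 0.1)  # 20
#' @export
hardening_law <- function(K_c = 10, D = 100, k_scale = NULL,
                          params = tip_params()) {
  stopifnot(K_c > 0, D > 0)
  if (is.null(k_scale))
    k_scale <- params$alpha / (params$C_Ca * sqrt(K_c * D))
  stopifnot(k_scale > 0)
  structure(list(K_c = K_c, D = D, k_scale = k_scale),
            class = "hardening_law")
}

#' Hardening rate from external calcium
#'
#' @param law A [hardening_law()].
#' @param C_Ca External calcium concentration, mM.
#' @return The hardening rate alpha (viscosity gain per unit residence
#'   time, MPa s per s).
#' @export
alpha_from_calcium <- function(law, C_Ca) {
  stopifnot(inherits(law, "hardening_law"), all(C_Ca >= 0))
  law$k_scale * C_Ca * sqrt(law$K_c * law$D)
}
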