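#' @keywords internal
"_PACKAGE"

## Canonical unit system: micrometre / second / MPa / osmol.
## R in MPa L mol^-1 K^-1; 1 L = 1e15 um^3.
R_GAS <- 8.314e-3
UM3_PER_L <- 1e15
V_W <- 18          # partial molar volume of water, cm^3/mol
CM_PER_UM <- 1e-4

#' Van 't Hoff osmotic pressure
#'
#' Converts an osmolarity to the osmotic pressure it exerts, \eqn{\Pi = RTc},
#' with \eqn{R = 8.314 \times 10^{-3}} MPa L mol\eqn{^{-1}} K\eqn{^{-1}}.
#'
#' @param c Osmolarity (Osm, i.e. osmol/L). Must be non-negative.
#' @param temperature Absolute temperature (K).
#' @return Osmotic pressure in MPa.
#' @examples
#' vant_hoff_pressure(0.3)  # baseline Lilium growth medium, ~0.744 MPa
#' @export
vant_hoff_pressure <- function(c, temperature = 298.15) {
  if (any(c < 0)) stop("osmolarity must be non-negative", call. = FALSE)
  R_GAS * temperature * c
}

## RT in MPa um^3 per osmol (for contents m in osmol, volumes in um^3)
rt_um3 <- function(temperature = 298.15) R_GAS * temperature * UM3_PER_L

#' Convert osmotic permeability between concentration and pressure form
#'
#' The concentration-form permeability \eqn{P_{os}} (cm/s) and the
#' pressure-form permeability (um MPa\eqn{^{-1}} s\eqn{^{-1}}) are related by
#' the van 't Hoff factor \eqn{V_w/RT} with \eqn{V_w = 18} cm\eqn{^3}/mol.
#'
#' @param P_os_cm Permeability in cm/s.
#' @param P_os_bar Permeability in um MPa^-1 s^-1.
#' @param temperature Absolute temperature (K).
#' @return The converted permeability.
#' @export
pos_cm_to_bar <- function(P_os_cm, temperature = 298.15) {
  rt_cm3 <- R_GAS * temperature * 1e3  # MPa cm^3 / mol
  P_os_cm * (V_W / rt_cm3) / CM_PER_UM
}

#' @rdname pos_cm_to_bar
#' @export
pos_bar_to_cm <- function(P_os_bar, temperature = 298.15) {
  rt_cm3 <- R_GAS * temperature * 1e3
  P_os_bar * CM_PER_UM * (rt_cm3 / V_W)
}
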