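#' Osmotic pressure of a solution
#'
#' Van 't Hoff pressure of the four ions plus the non-ionic osmolyte pool:
#' `pi = R*T*(Ca + H + K + Cl + Osm)` with concentrations converted from M
#' to mol m-3 internally. With a solute reflection coefficient of 1 this is
#' the full osmotic driving pressure.
#'
#' @param Ca,H,K,Cl,Osm_other Concentrations (M), non-negative.
#' @param constants Output of [physicalConstants()].
#' @return Osmotic pressure (Pa).
#' @examples
#' osmoticPressure(0, 0, 0, 0, 0.36)   # ~0.89 MPa at 25 C
#' @export
osmoticPressure <- function(Ca, H, K, Cl, Osm_other,
                            constants = physicalConstants()) {
  tot <- Ca + H + K + Cl + Osm_other
  if (any(tot < 0)) stop("concentrations must be non-negative")
  .RT_Pa_per_M(constants) * tot
}

#' Water-volume flux breakdown
#'
#' Osmotic water entry through the fixed tip osmotic zone:
#' `dv/dt = Lp * A_osm * ((pi_i - pi_o) - P)`. `A_osm` is a fixed membrane
#' area, not proportional to the cell volume, so a growing tube does not
#' accelerate exponentially.
#'
#' @param v Cell volume (m3), positive.
#' @param P Turgor pressure (Pa).
#' @param pi_i,pi_o Internal / media osmotic pressure (Pa).
#' @param Lp Membrane hydraulic conductivity (m s-1 Pa-1).
#' @param A_osm Osmotic-zone membrane area (m2).
#' @return Named list: `osmotic_inflow`, `turgor_outflow`, `net_water`
#'   (m3 s-1) and `rel_rate` (`net_water / v`, s-1).
#' @export
waterVolumeRate <- function(v, P, pi_i, pi_o, Lp, A_osm) {
  if (any(v <= 0)) stop("volume must be positive")
  inflow <- Lp * A_osm * (pi_i - pi_o)
  outflow <- Lp * A_osm * P
  net <- inflow - outflow
  list(osmotic_inflow = inflow, turgor_outflow = outflow,
       net_water = net, rel_rate = net / v)
}

#' Wall-chamber volume rate (Lockhart with tip-restricted extensibility)
#'
#' `dv/dt = v_ext * phi * max(P - Pc, 0) + (v / eps) * dP/dt`: plastic
#' yielding of the extensible tip region above the critical turgor, plus the
#' elastic response of the chamber. No plastic flow occurs below `Pc`.
#'
#' @param v Cell volume (m3).
#' @param v_ext Extensible tip-region volume (m3).
#' @param phi Wall extensibility (Pa-1 s-1), non-negative.
#' @param P Turgor (Pa).
#' @param Pc Critical turgor (Pa).
#' @param eps Volumetric elastic modulus (Pa).
#' @param dP_dt Rate of turgor change (Pa s-1).
#' @return `dv/dt` of the wall chamber (m3 s-1).
#' @export
wallChamberRate <- function(v, v_ext, phi, P, Pc, eps, dP_dt) {
  if (any(v <= 0)) stop("volume must be positive")
  if (any(phi < 0)) stop("extensibility must be non-negative")
  v_ext * phi * pmax(P - Pc, 0) + v / eps * dP_dt
}

#' Turgor dynamics
#'
#' Turgor is generated by the constraint that the relative change in water
#' volume equals the relative change in the wall-chamber volume:
#' `dP/dt = eps * ((Lp*A_osm/v)*(pi_i - pi_o - P) - (v_ext/v)*phi*max(P - Pc, 0))`.
#'
#' @inheritParams wallChamberRate
#' @param pi_i,pi_o Internal / media osmotic pressure (Pa).
#' @param params A [ModelParams-class] object supplying `Lp`, `A_osm`,
#'   `eps`, `Pc`, `v_ext`.
#' @return `dP/dt` (Pa s-1).
#' @export
turgorRhs <- function(v, P, pi_i, pi_o, phi, params) {
  if (any(v <= 0)) stop("volume must be positive")
  pv <- param(params)
  water <- pv[["Lp"]] * pv[["A_osm"]] / v * (pi_i - pi_o - P)
  plastic <- pv[["v_ext"]] / v * phi * pmax(P - pv[["Pc"]], 0)
  pv[["eps"]] * (water - plastic)
}

#' Steady turgor at frozen ions and wall viscosity
#'
#' Closed-form fixed point of the turgor equation when the osmotic pressures
#' and the extensibility are held constant (and `P > Pc`):
#' `P_ss = (Lp*A_osm*(pi_i - pi_o) + v_ext*phi*Pc) / (Lp*A_osm + v_ext*phi)`.
#'
#' @inheritParams turgorRhs
#' @return Steady-state turgor (Pa).
#' @export
steadyTurgor <- function(pi_i, pi_o, phi, params) {
  pv <- param(params)
  la <- pv[["Lp"]] * pv[["A_osm"]]
  vf <- pv[["v_ext"]] * phi
  (la * (pi_i - pi_o) + vf * pv[["Pc"]]) / (la + vf)
}

#' Convert a volume change to a growth rate
#'
#' For a cylinder `v = pi r^2 L`:
#' `dL/dt = (dv/dt - 2 pi r L dr/dt) / (pi r^2)`, reducing to
#' `dv/dt / (pi r^2)` at fixed radius.
#'
#' @param dv_dt Volume change (m3 s-1).
#' @param r Outer radius (m), positive.
#' @param dr_dt Radius change (m s-1).
#' @param L Tube length (m).
#' @return Growth rate `dL/dt` (m s-1).
#' @export
growthRateFromVolume <- function(dv_dt, r, dr_dt = 0, L = 0) {
  if (any(r <= 0)) stop("radius must be positive")
  (dv_dt - 2 * pi * r * L * dr_dt) / (pi * r^2)
}
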