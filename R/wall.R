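#' Calcium-dependent vesicle secretion rate
#'
#' Secretion of new wall material is proportional to tip cytosolic calcium,
#' `Rs = k2 * Ca_i`.
#'
#' @param Ca_i Cellular calcium concentration (M).
#' @param k2 Rate coefficient (m M-1 s-1).
#' @return Secretion rate (m s-1).
#' @export
secretionRate <- function(Ca_i, k2) {
  if (any(Ca_i < 0)) stop("Ca_i must be non-negative")
  k2 * Ca_i
}

#' Radius scaling of the secretion coefficient
#'
#' `k2 = k2a / r^2`: at fixed vesicle delivery, a wider tube spreads the
#' secreted material over a larger wall area.
#'
#' @param k2a Radius-independent coefficient (m3 M-1 s-1).
#' @param r Outer radius (m), positive.
#' @return `k2` (m M-1 s-1).
#' @export
k2FromRadius <- function(k2a, r) {
  if (any(r <= 0)) stop("radius must be positive")
  k2a / r^2
}

#' Wall-viscosity dynamics
#'
#' `d(eta)/dt = -eta * Rs / h + k1 * (eta_eq - eta)`: freshly secreted
#' material softens the wall (lowers viscosity) in proportion to the
#' secretion rate per unit wall thickness, while maturation relaxes the
#' viscosity back to its equilibrium value.
#'
#' @param eta Wall viscosity (Pa s).
#' @param Rs Secretion rate (m s-1).
#' @param h Wall thickness (m), positive.
#' @param eta_eq Equilibrium viscosity (Pa s).
#' @param k1 Relaxation rate (s-1).
#' @return `d(eta)/dt` (Pa).
#' @export
viscosityRhs <- function(eta, Rs, h, eta_eq, k1) {
  if (any(h <= 0)) stop("wall thickness must be positive")
  -eta * Rs / h + k1 * (eta_eq - eta)
}

#' Cell wall extensibility
#'
#' Extensibility is the inverse of the wall viscosity, `phi = 1/eta`.
#'
#' @param eta Wall viscosity (Pa s), positive.
#' @return Extensibility (Pa-1 s-1).
#' @export
extensibility <- function(eta) {
  if (any(eta <= 0)) stop("viscosity must be positive")
  1 / eta
}

#' Wall-thickness dynamics
#'
#' `dh/dt = -3 (r^2 - ri^2) / (2 r^2) * dL/dt + Rs`: elongation stretches
#' and thins the existing wall annulus; secretion thickens it.
#'
#' @param r,r_i Outer and inner radius (m), `0 < r_i < r`.
#' @param dL_dt Growth rate (m s-1).
#' @param Rs Secretion rate (m s-1).
#' @return `dh/dt` (m s-1).
#' @export
thicknessRhs <- function(r, r_i, dL_dt, Rs) {
  if (any(r_i <= 0) || any(r_i >= r)) stop("need 0 < r_i < r")
  -3 * (r^2 - r_i^2) / (2 * r^2) * dL_dt + Rs
}
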