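.stateNames <- function() {
  c("v", "P", "L", "eta", "h", "Ca_i", "H_i", "K_i", "Cl_i",
    "V", "p_Ca", "p_K", "n_K")
}

.outNames <- function() {
  c("pi_i", "pi_o", "phi", "osmotic_inflow", "turgor_outflow", "net_water",
    "wall_chamber_rate", "dP_dt", "dL_dt", "Rs", "k2",
    "I_vg1", "I_vg2", "I_vg3", "I_vg4", "I_vg5", "I_vg6",
    "I_sa1", "I_sa2", "r", "drdt", "eta_eq_now", "OV")
}

#' Full model right-hand side (reference implementation)
#'
#' Evaluates the time derivative of the complete 12-component cell state
#' (volume, turgor, length, wall viscosity and thickness, four ion
#' concentrations, membrane potential, two stretch-gate open fractions)
#' under a scenario protocol. This R implementation defines the model; the
#' compiled right-hand side used by [runSimulation()] must agree with it to
#' float precision and is cross-checked in the test suite.
#'
#' @param t Time (s), within the protocol span.
#' @param state Named numeric state vector, see `pollentube:::.stateNames()`.
#' @param params A [ModelParams-class] object.
#' @param protocol A [ScenarioProtocol-class] object.
#' @return `list(derivatives, outputs)` in deSolve convention; outputs hold
#'   the derived fluxes, pressures and currents.
#' @export
cellRhs <- function(t, state, params, protocol) {
  s <- as.list(state)
  pv <- param(params)
  cst <- params@constants
  ext <- protocolAt(protocol, t)

  r <- ext$r
  h <- max(s$h, 1e-9)           # guard: Eq for eta divides by h
  eta <- max(s$eta, 1e3)
  Ca <- max(s$Ca_i, 0); H <- max(s$H_i, 0)
  K <- max(s$K_i, 0); Cl <- max(s$Cl_i, 0)
  p_Ca <- min(max(s$p_Ca, 0), 1)
  p_K <- min(max(s$p_K, 0), 1)
  n_K <- min(max(s$n_K, 0), 1)

  OV <- pv[["ov_scale"]] * 2 / r
  pi_i <- osmoticPressure(Ca, H, K, Cl, ext$Osm_i, cst)
  pi_o <- osmoticPressure(ext$Ca_o, ext$H_o, ext$K_o, ext$Cl_o, ext$Osm_o,
                          cst)

  water <- waterVolumeRate(s$v, s$P, pi_i, pi_o, pv[["Lp"]], pv[["A_osm"]])
  dv <- water$net_water
  phi <- 1 / eta
  plastic_rel <- pv[["v_ext"]] / s$v * phi * max(s$P - pv[["Pc"]], 0)
  dP <- pv[["eps"]] * (water$rel_rate - plastic_rel)
  dL <- growthRateFromVolume(dv, r, ext$drdt, s$L)

  k2 <- ext$fusion_scale * k2FromRadius(pv[["k2a"]], r)
  Rs <- secretionRate(Ca, k2)
  deta <- viscosityRhs(eta, Rs, h, ext$eta_eq, pv[["k1"]])
  r_i <- max(r - h, 0.1 * r)
  dh <- thicknessRhs(r, r_i, dL, Rs)

  rates <- stretchGateRates(s$P, pv[["kOC0"]], pv[["kCO0"]], pv[["ka"]])
  dp_Ca <- gateRhs(p_Ca, rates$kOC, rates$kCO)
  dp_K <- gateRhs(p_K, rates$kOC, rates$kCO)

  st <- list(V = s$V, Ca_i = Ca, H_i = H, K_i = K, Cl_i = Cl,
             Ca_o = ext$Ca_o, H_o = ext$H_o, K_o = ext$K_o, Cl_o = ext$Cl_o,
             p_open_Ca = p_Ca, p_open_K = p_K, n_K = n_K)
  Ivg <- voltageGatedCurrents(st, params)
  Isa <- stretchCurrents(st, params)
  dV <- membranePotentialRhs(c(Ivg, Isa), pv[["Cm"]])

  dion <- ionRhs(list(Ca_i = Ca, H_i = H, K_i = K, Cl_i = Cl),
                 c(Ivg, Isa), OV, cst$F, water$rel_rate, params)

  n_inf <- boltzmannGate(s$V, pv[["Vh_vg2"]], pv[["s_vg2"]])
  dn <- (n_inf - n_K) / pv[["tau_n"]]

  deriv <- c(dv, dP, dL, deta, dh, dion, dV, dp_Ca, dp_K, dn)
  names(deriv) <- .stateNames()
  out <- c(pi_i = pi_i, pi_o = pi_o, phi = phi,
           osmotic_inflow = water$osmotic_inflow,
           turgor_outflow = water$turgor_outflow,
           net_water = water$net_water,
           wall_chamber_rate = pv[["v_ext"]] * phi *
             max(s$P - pv[["Pc"]], 0) + s$v / pv[["eps"]] * dP,
           dP_dt = dP, dL_dt = dL, Rs = Rs, k2 = k2,
           Ivg, I_sa1 = unname(Isa["I_sa1"]), I_sa2 = unname(Isa["I_sa2"]),
           r = r, drdt = ext$drdt, eta_eq_now = ext$eta_eq, OV = OV)
  list(deriv, out)
}
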