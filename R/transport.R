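#' Ohmic transporter current
#'
#' @param g Conductance (S m-2).
#' @param V Membrane voltage (V).
#' @param E Reversal potential (V).
#' @return Current density `g * (V - E)` (A m-2), positive outward.
#' @export
ohmicCurrent <- function(g, V, E) g * (V - E)

#' Goldman-Hodgkin-Katz constant-field current
#'
#' \deqn{I = g V \frac{c_i - c_e e^{-zV/V_{ref}}}{1 - e^{-zV/V_{ref}}}}
#' with the series limit \eqn{g V_{ref} (c_i - c_e)/z} substituted for
#' \eqn{|zV/V_{ref}| < 10^{-6}} to avoid the 0/0 at the origin. The current
#' vanishes at the ion's Nernst potential and is positive outward. `g` is a
#' per-molar conductance (A m-2 V-1 M-1); `ci`, `ce` in M.
#'
#' @param g Per-molar conductance (A m-2 V-1 M-1).
#' @param V Membrane voltage (V).
#' @param z Ion valence (non-zero integer).
#' @param ci,ce Internal / external concentration (M).
#' @param Vref Thermal voltage RT/F (V).
#' @return Current density (A m-2).
#' @examples
#' pc <- physicalConstants()
#' E <- pc$Vref / 1 * log(0.1 / 0.01)          # K+ Nernst potential
#' ghkCurrent(1, E, 1, 0.01, 0.1, pc$Vref)     # ~0 at reversal
#' @export
ghkCurrent <- function(g, V, z, ci, ce, Vref = physicalConstants()$Vref) {
  if (any(z == 0)) stop("valence z must be non-zero")
  if (any(ci < 0) || any(ce < 0)) stop("concentrations must be non-negative")
  n <- max(length(g), length(V), length(z), length(ci), length(ce))
  g <- rep_len(g, n); V <- rep_len(V, n); z <- rep_len(z, n)
  ci <- rep_len(ci, n); ce <- rep_len(ce, n)
  x <- z * V / Vref
  small <- abs(x) < 1e-6
  out <- numeric(n)
  if (any(!small)) {
    em <- exp(-x[!small])
    out[!small] <- g[!small] * V[!small] *
      (ci[!small] - ce[!small] * em) / (1 - em)
  }
  if (any(small))
    out[small] <- g[small] * Vref * (ci[small] - ce[small]) / z[small]
  out
}

#' Two-state Boltzmann voltage-gating factor
#'
#' Open probability `1/(1 + exp((Vh - V)/s))` increasing with depolarisation
#' for `s > 0`; pass a negative `s` for channels activated by
#' hyperpolarisation.
#'
#' @param V Membrane voltage (V).
#' @param Vh Half-activation voltage (V).
#' @param s Slope factor (V).
#' @return Open fraction in (0, 1).
#' @export
boltzmannGate <- function(V, Vh, s) 1 / (1 + exp((Vh - V) / s))

#' Turgor-dependent stretch-channel gating rates
#'
#' Opening is promoted by turgor: the closed-to-open rate grows exponentially
#' with pressure, `kCO = kCO0 * exp(ka * P)`, while the open-to-closed rate
#' stays at its zero-turgor value, `kOC = kOC0`.
#'
#' @param P Turgor pressure (Pa).
#' @param kOC0,kCO0 Zero-turgor rate constants (s-1).
#' @param ka Pressure-activation strength (Pa-1), non-negative.
#' @return List with `kOC` and `kCO` (s-1).
#' @export
stretchGateRates <- function(P, kOC0, kCO0, ka) {
  stopifnot(all(is.finite(P)), ka >= 0, kOC0 >= 0, kCO0 >= 0)
  # closed->open rate capped at 1e4 s-1: the open fraction saturates long
  # before, and the cap keeps the gate ODE integrable under extreme turgor
  list(kOC = rep_len(kOC0, length(P)),
       kCO = pmin(kCO0 * exp(pmin(ka * P, 700)), 1e4))
}

#' Open-fraction kinetics of a two-state channel
#'
#' Mass-action relaxation of the open fraction,
#' `dp/dt = kCO * (1 - p) - kOC * p`, with fixed point
#' `kCO / (kCO + kOC)`.
#'
#' @param p_open Open fraction in \[0, 1\].
#' @param kOC,kCO Transition rates (s-1).
#' @return Time derivative of the open fraction (s-1).
#' @export
gateRhs <- function(p_open, kOC, kCO) {
  if (any(p_open < 0 | p_open > 1)) stop("p_open must lie in [0, 1]")
  kCO * (1 - p_open) - kOC * p_open
}

#' Stretch-activated channel currents
#'
#' GHK currents of the stretch-activated Ca2+ (z = 2) and K+ (z = 1)
#' channels, scaled by their gate open fractions. The optional
#' stretch-activated Cl- variant (off by default, `g_Cl_sa = 0`) shares the
#' mechanosensitive Ca-gate open fraction.
#'
#' @param state Named list/vector with `V`, `Ca_i`, `K_i`, `Cl_i`,
#'   `p_open_Ca`, `p_open_K` and external `Ca_o`, `K_o`, `Cl_o`.
#' @param params A [ModelParams-class] object.
#' @return Named numeric `c(I_sa1, I_sa2, I_sa3)` (A m-2); `I_sa3` is the
#'   optional Cl- component.
#' @export
stretchCurrents <- function(state, params) {
  v <- param(params)
  Vref <- params@constants$Vref
  s <- as.list(state)
  I_sa1 <- s$p_open_Ca *
    ghkCurrent(v[["g_Ca_sa"]], s$V, 2, s$Ca_i, s$Ca_o, Vref)
  I_sa2 <- s$p_open_K *
    ghkCurrent(v[["g_K_sa"]], s$V, 1, s$K_i, s$K_o, Vref)
  I_sa3 <- if (v[["g_Cl_sa"]] > 0)
    s$p_open_Ca * ghkCurrent(v[["g_Cl_sa"]], s$V, -1, s$Cl_i, s$Cl_o, Vref)
  else 0
  c(I_sa1 = I_sa1, I_sa2 = I_sa2, I_sa3 = I_sa3)
}

#' Voltage-gated transporter currents
#'
#' The six-transporter set of the four-ion balance, each an ohmic or GHK
#' kernel times a two-state Boltzmann gating factor: vg1 inward-rectifier K+
#' (GHK, hyperpolarisation-activated), vg2 outward-rectifier K+ (GHK,
#' depolarisation-activated through a slow first-order activation gate
#' `n_K` with time constant `tau_n`; the instantaneous Boltzmann value is
#' used when no gate state is supplied), vg3 voltage-gated Ca2+ (GHK,
#' z = 2), vg4 H+
#' pump (saturating voltage-dependent efflux with Michaelis dependence on
#' internal H+), vg5 Cl-/2H+ symporter (ohmic about its combined reversal
#' `2 E_H - E_Cl`, net charge +1 per cycle, active at hyperpolarised
#' voltages), vg6 depolarisation-activated
#' anion channel (GHK, z = -1). The GHK form keeps every channel current
#' bounded when an ion pool depletes. All currents positive outward.
#'
#' @param state Named list/vector with `V`, the four internal and external
#'   ion concentrations (`Ca_i`, ..., `Cl_o`) in M.
#' @param params A [ModelParams-class] object.
#' @return Named numeric `c(I_vg1, ..., I_vg6)` (A m-2).
#' @export
voltageGatedCurrents <- function(state, params) {
  v <- param(params)
  Vref <- params@constants$Vref
  s <- as.list(state)
  V <- s$V
  E_H <- Vref * log(max(s$H_o, 1e-30) / max(s$H_i, 1e-30))
  E_Cl <- -Vref * log(max(s$Cl_o, 1e-12) / max(s$Cl_i, 1e-12))
  I_vg1 <- boltzmannGate(V, v[["Vh_vg1"]], -v[["s_vg1"]]) *
    ghkCurrent(v[["g_vg1"]], V, 1, s$K_i, s$K_o, Vref)
  n <- if (is.null(s$n_K))
    boltzmannGate(V, v[["Vh_vg2"]], v[["s_vg2"]]) else s$n_K
  I_vg2 <- n * ghkCurrent(v[["g_vg2"]], V, 1, s$K_i, s$K_o, Vref)
  I_vg3 <- boltzmannGate(V, v[["Vh_vg3"]], v[["s_vg3"]]) *
    ghkCurrent(v[["g_vg3"]], V, 2, s$Ca_i, s$Ca_o, Vref)
  I_vg4 <- v[["I_pump_max"]] *
    boltzmannGate(V, v[["Vh_pump"]], v[["s_pump"]]) *
    s$H_i / (s$H_i + v[["Km_pump"]])
  I_vg5 <- v[["g_vg5"]] * boltzmannGate(V, v[["Vh_vg5"]], -v[["s_vg5"]]) *
    (V - (2 * E_H - E_Cl))
  I_vg6 <- boltzmannGate(V, v[["Vh_vg6"]], v[["s_vg6"]]) *
    ghkCurrent(v[["g_vg6"]], V, -1, s$Cl_i, s$Cl_o, Vref)
  c(I_vg1 = I_vg1, I_vg2 = I_vg2, I_vg3 = I_vg3,
    I_vg4 = I_vg4, I_vg5 = I_vg5, I_vg6 = I_vg6)
}

#' Membrane-potential balance
#'
#' Charge balance across the membrane capacitance:
#' `dV/dt = -(sum of all transporter currents)/Cm`, currents positive
#' outward.
#'
#' @param currents Numeric vector of signed current densities (A m-2).
#' @param Cm Specific membrane capacitance (F m-2).
#' @return `dV/dt` (V s-1).
#' @export
membranePotentialRhs <- function(currents, Cm) {
  stopifnot(Cm > 0)
  -sum(currents) / Cm
}
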