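#' Four-ion concentration dynamics
#'
#' Rate of change of the cellular Ca2+, H+, K+ and Cl- concentrations. Each
#' ion balances (i) its transporter fluxes, scaled by the
#' surface-to-volume ratio `OV` and converted through `z F` (Ca2+ divides by
#' `2F`; the Cl- current combination is `-I_vg6 - I_sa3 + I_vg5`, and H+
#' receives `2 I_vg5` from the 2H+/Cl- symporter stoichiometry), (ii) linear
#' relaxation to its shank set-point, (iii) dilution by relative volume
#' growth, and (iv), for Ca2+ and H+ only, a linear buffering term of
#' configurable strength (default 0; buffering is folded into the
#' relaxation rates of the shipped parameter set).
#'
#' @param ions Named numeric: `Ca_i`, `H_i`, `K_i`, `Cl_i` (M), non-negative.
#' @param currents Named numeric with `I_vg1` ... `I_vg6`, `I_sa1`, `I_sa2`
#'   and optionally `I_sa3` (A m-2, positive outward).
#' @param OV Transporter surface-to-volume ratio (m-1).
#' @param F Faraday constant (C mol-1).
#' @param rel_vol_rate Relative volume growth `(1/v) dv/dt` (s-1).
#' @param params A [ModelParams-class] object.
#' @return Named numeric derivative vector (M s-1).
#' @export
ionRhs <- function(ions, currents, OV, F, rel_vol_rate, params) {
  ions <- as.list(ions)
  if (any(unlist(ions[c("Ca_i", "H_i", "K_i", "Cl_i")]) < 0))
    stop("ion concentrations must be non-negative")
  stopifnot(is.finite(rel_vol_rate))
  cur <- as.list(currents)
  if (is.null(cur$I_sa3)) cur$I_sa3 <- 0
  v <- param(params)
  toM <- 1e-3  # mol m-3 -> M
  dCa <- -OV * (cur$I_vg3 + cur$I_sa1) / (2 * F) * toM -
    v[["k_relax_Ca"]] * (ions$Ca_i - v[["setpoint_Ca"]]) -
    rel_vol_rate * ions$Ca_i -
    v[["buffer_Ca"]] * (ions$Ca_i - v[["setpoint_Ca"]])
  dH <- -OV * (cur$I_vg4 + 2 * cur$I_vg5) / F * toM -
    v[["k_relax_H"]] * (ions$H_i - v[["setpoint_H"]]) -
    rel_vol_rate * ions$H_i -
    v[["buffer_H"]] * (ions$H_i - v[["setpoint_H"]])
  dK <- -OV * (cur$I_vg1 + cur$I_vg2 + cur$I_sa2) / F * toM -
    v[["k_relax_K"]] * (ions$K_i - v[["setpoint_K"]]) -
    rel_vol_rate * ions$K_i
  dCl <- -OV * (-cur$I_vg6 - cur$I_sa3 + cur$I_vg5) / F * toM -
    v[["k_relax_Cl"]] * (ions$Cl_i - v[["setpoint_Cl"]]) -
    rel_vol_rate * ions$Cl_i
  c(Ca_i = dCa, H_i = dH, K_i = dK, Cl_i = dCl)
}
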