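# Shared fixtures: a small fast parameter set and synthetic series builders.

fastParams <- function(...) {
  p <- defaultParams()
  setParams(p, ...)
}

# Synthetic oscillatory trajectory with closed-form columns that satisfy the
# water-side and wall-side decomposition identities exactly; used as an
# independent oracle for the regulation coefficients.
syntheticTrajectory <- function(params, t, pi_i, pi_o, P, v = 4e-14,
                                phi = NULL) {
  pv <- param(params)
  la <- pv[["Lp"]] * pv[["A_osm"]]
  net <- la * (pi_i - pi_o - P)
  dP <- c(diff(P) / diff(t), 0)
  dP[length(dP)] <- dP[length(dP) - 1L]
  if (is.null(phi)) {
    # choose phi so that the chamber identity holds pointwise:
    # net = v_ext*phi*(P-Pc) + (v/eps)*dP
    phi <- (net - v / pv[["eps"]] * dP) /
      (pv[["v_ext"]] * (P - pv[["Pc"]]))
  }
  d <- data.frame(time = t, v = v, P = P, pi_i = pi_i, pi_o = pi_o,
                  net_water = net, dP_dt = dP, phi = phi)
  d$wall_yield_rate <- pv[["v_ext"]] * d$phi * pmax(d$P - pv[["Pc"]], 0)
  prot <- scenarioProtocol(range(t) + c(0, 1), params)
  new("Trajectory", data = d, params = params, protocol = prot,
      solver = solverSettings())
}

# Alternating large/small waveform with analytically known peak times:
# f(x) = sin(x) - a*cos(2x) has its large maxima at x = pi/2 + 2*k*pi and,
# for a > 1/4... (small local maxima at x = 3*pi/2 when 4a > 1)
largeSmallWave <- function(t, period = 50, a = 0.45) {
  x <- 2 * pi * t / period
  sin(x) - a * cos(2 * x)
}
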