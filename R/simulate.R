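#' Cold-start initial state
#'
#' Initial conditions built from the parameter set: cylinder volume from
#' `r0`/`L0`, set-point ion concentrations, turgor 0.2 MPa, wall viscosity at
#' its equilibrium value, thickness `h0`, membrane potential -0.1 V and
#' stretch gates at their pressure equilibrium. Useful for burn-in runs; the
#' shipped scenarios start from the stored calibrated limit-cycle state
#' ([calibratedInit()]) instead.
#'
#' @param params A [ModelParams-class] object.
#' @return Named numeric state vector.
#' @export
initState <- function(params) {
  v <- param(params)
  P0 <- 2e5
  rates <- stretchGateRates(P0, v[["kOC0"]], v[["kCO0"]], v[["ka"]])
  p0 <- rates$kCO / (rates$kCO + rates$kOC)
  st <- c(v = pi * v[["r0"]]^2 * v[["L0"]], P = P0, L = v[["L0"]],
          eta = v[["eta_eq"]], h = v[["h0"]],
          Ca_i = v[["setpoint_Ca"]], H_i = v[["setpoint_H"]],
          K_i = v[["setpoint_K"]], Cl_i = v[["setpoint_Cl"]],
          V = -0.1, p_Ca = p0, p_K = p0,
          n_K = boltzmannGate(-0.1, v[["Vh_vg2"]], v[["s_vg2"]]))
  names(st) <- .stateNames()
  st
}

#' Stored calibrated limit-cycle state
#'
#' The state saved at the end of a converged isotonic run with the shipped
#' calibrated parameters; scenarios started here show stationary
#' oscillations from time zero, without a burn-in.
#'
#' @return Named numeric state vector.
#' @export
calibratedInit <- function() {
  path <- system.file("extdata", "calibrated_params.yaml",
                      package = "pollentube", mustWork = TRUE)
  cfg <- loadConfig(path)
  if (is.null(cfg$init)) stop("shipped config has no init section")
  cfg$init
}

#' Default solver settings
#'
#' @param rtol Relative tolerance of the stiff integrator.
#' @param sample_dt Output sampling interval (s).
#' @param method deSolve method name (default `"lsoda"`).
#' @return List of solver settings for [runSimulation()].
#' @export
solverSettings <- function(rtol = 1e-8, sample_dt = 0.1, method = "lsoda") {
  list(rtol = rtol, sample_dt = sample_dt, method = method,
       maxsteps = 5e5)
}

# per-state absolute tolerances scaled to typical magnitudes
.atolVector <- function() {
  c(v = 1e-22, P = 1e-4, L = 1e-12, eta = 1e-2, h = 1e-15,
    Ca_i = 1e-14, H_i = 1e-15, K_i = 1e-10, Cl_i = 1e-10,
    V = 1e-10, p_Ca = 1e-10, p_K = 1e-10, n_K = 1e-10)
}

#' Run the coupled growth model
#'
#' Integrates the full 13-state model (water volume, turgor, length, wall
#' viscosity and thickness, four ions, membrane potential, stretch gates and
#' the slow rectifier activation gate)
#' with an adaptive stiff solver, restarting at every protocol breakpoint.
#' The right-hand side is compiled; it is the exact counterpart of
#' [cellRhs()].
#'
#' @param params A [ModelParams-class] object.
#' @param protocol A [ScenarioProtocol-class] object.
#' @param t_span Length-2 time span (s); must lie within the protocol span.
#' @param init Named initial state; default [initState()] from `params`.
#' @param solver Settings from [solverSettings()].
#' @return A [Trajectory-class] object. Besides the state and flux columns
#'   (SI units) the data carry the convenience columns `growth_um_min`
#'   (\eqn{\mu m} min^-1), `volume_change_um3_s` (\eqn{\mu m^3} s^-1),
#'   `P_MPa`, `phi_MPa_s` (MPa^-1 s^-1) and `wall_yield_rate` (m3 s^-1,
#'   the plastic part of the chamber rate).
#' @export
runSimulation <- function(params, protocol, t_span = protocol@span,
                          init = NULL, solver = solverSettings()) {
  stopifnot(is(params, "ModelParams"), is(protocol, "ScenarioProtocol"))
  if (t_span[1L] < protocol@span[1L] || t_span[2L] > protocol@span[2L])
    stop("t_span outside the protocol span")
  if (is.null(init)) init <- initState(params)
  init <- init[.stateNames()]
  if (any(is.na(init))) stop("init must name all state components")

  forcings <- .protocolForcings(protocol)
  breaks <- .protocolBreaks(protocol)
  breaks <- breaks[breaks > t_span[1L] & breaks < t_span[2L]]
  edges <- unique(c(t_span[1L], breaks, t_span[2L]))

  pieces <- vector("list", length(edges) - 1L)
  y <- init
  for (k in seq_len(length(edges) - 1L)) {
    tt <- seq(edges[k], edges[k + 1L], by = solver$sample_dt)
    if (tt[length(tt)] < edges[k + 1L]) tt <- c(tt, edges[k + 1L])
    out <- deSolve::ode(
      y = y, times = tt, func = "ptube_derivs", parms = .packParams(params),
      dllname = "pollentube", initfunc = "ptube_init",
      initforc = "ptube_forc", forcings = forcings,
      method = solver$method, rtol = solver$rtol, atol = .atolVector(),
      nout = 23L, outnames = .outNames(), maxsteps = solver$maxsteps)
    istate <- attr(out, "istate")
    if (!is.null(istate) && istate[1L] < 0 || any(!is.finite(out))) {
      bad <- which(!stats::complete.cases(out))[1L]
      t_bad <- if (is.na(bad)) edges[k + 1L] else out[bad, "time"]
      comp <- if (!is.na(bad))
        colnames(out)[which(!is.finite(out[bad, ]))[1L]] else "unknown"
      stop(sprintf(
        "integration failed near t = %.6g s (first bad component: %s)",
        t_bad, comp))
    }
    pieces[[k]] <- if (k == 1L) out else out[-1L, , drop = FALSE]
    y <- out[nrow(out), 1L + seq_along(.stateNames())]
    names(y) <- .stateNames()
  }
  d <- as.data.frame(do.call(rbind, pieces))
  pv <- param(params)
  d$wall_yield_rate <- pv[["v_ext"]] * d$phi * pmax(d$P - pv[["Pc"]], 0)
  d$growth_um_min <- d$dL_dt * 6e7
  d$volume_change_um3_s <- d$net_water * 1e18
  d$P_MPa <- d$P * 1e-6
  d$phi_MPa_s <- d$phi * 1e6
  if (any(d$h <= 1.5e-9))
    warning("wall thickness reached the 1 nm guard; results degenerate")
  new("Trajectory", data = d, params = params, protocol = protocol,
      solver = solver)
}

#' Access trajectory data
#'
#' @param traj A [Trajectory-class] object.
#' @return The underlying data.frame.
#' @export
trajectoryData <- function(traj) {
  stopifnot(is(traj, "Trajectory"))
  traj@data
}

#' Extract one series from a trajectory
#'
#' @param traj A [Trajectory-class] object.
#' @param var Column name.
#' @param from,to Optional time window (s).
#' @return data.frame with `time` and `value`.
#' @export
trajectorySeries <- function(traj, var, from = -Inf, to = Inf) {
  d <- trajectoryData(traj)
  if (!var %in% names(d)) stop("no column '", var, "' in trajectory")
  keep <- d$time >= from & d$time <= to
  data.frame(time = d$time[keep], value = d[[var]][keep])
}
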