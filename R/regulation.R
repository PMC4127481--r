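# Period-averaged terms of the water-side and wall-side decompositions for
# one oscillatory state. `window = NULL` takes the last exact period of the
# analysed tail.
.stateAverages <- function(traj, window = NULL,
                           settings = oscillationSettings()) {
  d <- trajectoryData(traj)
  if (is.null(window)) {
    osc <- oscillationOf(traj, "net_water", settings = settings)
    if (!osc@oscillatory)
      stop("trajectory is not oscillatory; cannot take exact-period averages")
    window <- exactPeriodWindow(osc)
  }
  pv <- param(traj@params)
  la <- pv[["Lp"]] * pv[["A_osm"]]
  avg <- function(col) periodAverage(d$time, d[[col]], window)
  PmPc <- d$P - pv[["Pc"]]
  if (any(PmPc[d$time >= window[1] & d$time <= window[2]] <= 0)) {
    t_bad <- d$time[which(d$time >= window[1] & PmPc <= 0)[1L]]
    stop(sprintf("P <= Pc at t = %.6g s: wall-side log terms undefined",
                 t_bad))
  }
  elastic_corr <- (d$v / pv[["eps"]] * d$dP_dt) / d$wall_yield_rate
  logv <- function(x) periodAverage(d$time, log(x), window)
  list(window = window,
       dvdt = avg("net_water"),
       la_pi_i = la * avg("pi_i"),
       la_pi_o = la * avg("pi_o"),
       la_P = la * avg("P"),
       log_dvdt = logv(pmax(d$net_water, 1e-300)),
       log_vext_phi = logv(pv[["v_ext"]] * d$phi),
       log_PmPc = logv(PmPc),
       log_elastic = logv(pmax(1 + elastic_corr, 1e-300)))
}

#' Water-side regulation coefficients
#'
#' Additive decomposition of the between-state change in period-averaged
#' water volume change into the contributions of cellular osmotic pressure,
#' media osmotic pressure and turgor:
#' \deqn{R_{\pi_i}^w = \frac{\Delta \overline{L_p A_{osm} \pi_i}}{\Delta \overline{dv/dt}},\quad
#'       R_{\pi_o}^w = -\frac{\Delta \overline{L_p A_{osm} \pi_o}}{\Delta \overline{dv/dt}},\quad
#'       R_{P}^w = -\frac{\Delta \overline{L_p A_{osm} P}}{\Delta \overline{dv/dt}}}
#' where \eqn{\Delta} is the O1 minus O2 difference of exact-period
#' averages. The three coefficients sum to 1 identically.
#'
#' @param trajO1,trajO2 Oscillatory [Trajectory-class] objects for the two
#'   growth states.
#' @param windowO1,windowO2 Optional explicit averaging windows (s).
#' @param settings Peak-detection settings used when windows are derived.
#' @return Named list with the three coefficients, their sum, and the
#'   averaged terms per state.
#' @export
waterRegulationCoefficients <- function(trajO1, trajO2, windowO1 = NULL,
                                        windowO2 = NULL,
                                        settings = oscillationSettings()) {
  a1 <- .stateAverages(trajO1, windowO1, settings)
  a2 <- .stateAverages(trajO2, windowO2, settings)
  dd <- a1$dvdt - a2$dvdt
  scale <- max(abs(a1$dvdt), abs(a2$dvdt), .Machine$double.xmin)
  if (abs(dd) < 1e-6 * scale)
    stop("degenerate comparison: the two states have indistinguishable ",
         "average volume change")
  R_pi_i <- (a1$la_pi_i - a2$la_pi_i) / dd
  R_pi_o <- -(a1$la_pi_o - a2$la_pi_o) / dd
  R_P <- -(a1$la_P - a2$la_P) / dd
  list(R_pi_i_w = R_pi_i, R_pi_o_w = R_pi_o, R_P_w = R_P,
       water_sum = R_pi_i + R_pi_o + R_P,
       averages = list(O1 = a1, O2 = a2))
}

#' Wall-side regulation coefficients
#'
#' Logarithmic decomposition of the wall-chamber volume change,
#' `log(dv/dt) = log(v_ext*phi) + log(P - Pc) + log(1 + elastic correction)`,
#' averaged over an exact period in each state; each coefficient is the
#' between-state difference of one averaged log term over the difference of
#' the averaged `log(dv/dt)`. The three coefficients (extensibility, turgor,
#' temporal turgor change) sum to 1. Natural logarithms are used; requires
#' `P > Pc` throughout both windows.
#'
#' @inheritParams waterRegulationCoefficients
#' @return Named list with `R_phi_c`, `R_P_c`, `R_O_c`, `wall_sum` and the
#'   averaged terms per state.
#' @export
wallRegulationCoefficients <- function(trajO1, trajO2, windowO1 = NULL,
                                       windowO2 = NULL,
                                       settings = oscillationSettings()) {
  a1 <- .stateAverages(trajO1, windowO1, settings)
  a2 <- .stateAverages(trajO2, windowO2, settings)
  dd <- a1$log_dvdt - a2$log_dvdt
  if (abs(dd) < 1e-9)
    stop("degenerate comparison: the two states have indistinguishable ",
         "average log volume change")
  R_phi <- (a1$log_vext_phi - a2$log_vext_phi) / dd
  R_P <- (a1$log_PmPc - a2$log_PmPc) / dd
  R_O <- (a1$log_elastic - a2$log_elastic) / dd
  list(R_phi_c = R_phi, R_P_c = R_P, R_O_c = R_O,
       wall_sum = R_phi + R_P + R_O,
       averages = list(O1 = a1, O2 = a2))
}

#' Full regulation report for a pair of oscillatory states
#'
#' @inheritParams waterRegulationCoefficients
#' @param labels Character length-2 naming the states.
#' @return A [RegulationReport-class] object.
#' @export
regulationReport <- function(trajO1, trajO2, labels = c("O1", "O2"),
                             settings = oscillationSettings()) {
  w <- waterRegulationCoefficients(trajO1, trajO2, settings = settings)
  c_ <- wallRegulationCoefficients(trajO1, trajO2, settings = settings)
  avg <- rbind(
    data.frame(state = labels[1L], w$averages$O1[-1L],
               window_start = w$averages$O1$window[1L],
               window_end = w$averages$O1$window[2L]),
    data.frame(state = labels[2L], w$averages$O2[-1L],
               window_start = w$averages$O2$window[1L],
               window_end = w$averages$O2$window[2L]))
  new("RegulationReport",
      water = c(R_pi_i_w = w$R_pi_i_w, R_pi_o_w = w$R_pi_o_w,
                R_P_w = w$R_P_w, water_sum = w$water_sum),
      wall = c(R_phi_c = c_$R_phi_c, R_P_c = c_$R_P_c, R_O_c = c_$R_O_c,
               wall_sum = c_$wall_sum),
      averages = avg,
      windows = list(O1 = w$averages$O1$window, O2 = w$averages$O2$window),
      labels = labels)
}
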