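.scenarioNames <- function() {
  c("isotonic", "hypotonic_018", "hypertonic_116", "calcium_shift",
    "ph_shift", "raba4d", "viscosity_ramp", "oil_injection",
    "osmolarity_sweep", "viscosity_sweep")
}

# Non-ionic media osmolyte needed for a target total media osmolarity given
# the reference media ion composition.
.osmOtherFor <- function(pv, total) {
  ions <- pv[["Ca_o_ref"]] + pv[["H_o_ref"]] + pv[["K_o_ref"]] +
    pv[["Cl_o_ref"]]
  if (total < ions) stop("media osmolarity below its ionic content")
  total - ions
}

#' Build a named perturbation scenario
#'
#' Encodes the in-silico experiments as scenario protocols: osmotic
#' up/down-shifts with their prescribed radius ramps, media Ca2+ and pH
#' shifts, the Raba4d-knockout fusion-rate reduction, the equilibrium
#' wall-viscosity ramp schedule, oil-injection increases of cellular
#' osmolarity, and constant-condition variants used for sweeps. Step changes
#' are encoded as 1 s linear ramps; perturbations start at 7200 s unless
#' noted.
#'
#' @param name One of `"isotonic"`, `"hypotonic_018"`, `"hypertonic_116"`,
#'   `"calcium_shift"`, `"ph_shift"`, `"raba4d"`, `"viscosity_ramp"`,
#'   `"oil_injection"`, `"osmolarity_sweep"`, `"viscosity_sweep"`.
#' @param params Base parameter set (default [calibratedParams()]).
#' @param t_end Simulation end time (s); scenario-specific default.
#' @param overrides Named list of scenario knobs: `Osm_total` (media
#'   osmolarity, Osm, for `osmolarity_sweep`), `eta_eq` (Pa s, for the
#'   sweeps), `radius` (m), `t_shift` (perturbation time, s).
#' @return List with elements `params`, `protocol` and `t_end`.
#' @examples
#' \donttest{
#' sc <- buildScenario("isotonic")
#' }
#' @export
buildScenario <- function(name, params = calibratedParams(), t_end = NULL,
                          overrides = list()) {
  if (!name %in% .scenarioNames())
    stop("unknown scenario '", name, "'; valid names: ",
         paste(.scenarioNames(), collapse = ", "))
  pv <- param(params)
  ts <- overrides$t_shift %||% 7200
  # Raba4d-knockout tubes are about twice as wide (wt ~6 um, mutant ~12 um)
  r0 <- overrides$radius %||% (if (name == "raba4d") 12e-6 else pv[["r0"]])
  params <- setParams(params, r0 = r0)
  pv <- param(params)

  dflt_end <- switch(name,
    isotonic = 7200, hypotonic_018 = 15000, hypertonic_116 = 15000,
    calcium_shift = 14400, ph_shift = 14400, raba4d = 7200,
    viscosity_ramp = 15000, oil_injection = 14400,
    osmolarity_sweep = 7200, viscosity_sweep = 7200)
  t_end <- t_end %||% dflt_end
  span <- c(0, t_end)

  courses <- switch(name,
    isotonic = list(),
    hypotonic_018 = list(
      Osm_o = .stepCourse(.osmOtherFor(pv, 0.36), .osmOtherFor(pv, 0.18),
                          ts, span),
      r = pwlCourse(c(0, ts, ts + 1800, max(t_end, ts + 1801)),
                    c(r0, r0, 1.1 * r0, 1.1 * r0))),
    hypertonic_116 = list(
      Osm_o = .stepCourse(.osmOtherFor(pv, 0.36), .osmOtherFor(pv, 1.16),
                          ts, span),
      r = pwlCourse(c(0, ts, ts + 1800, max(t_end, ts + 1801)),
                    c(r0, r0, 0.7 * r0, 0.7 * r0))),
    calcium_shift = list(
      Ca_o = pwlCourse(c(0, ts, ts + 1, ts + 3600, ts + 3601,
                         max(t_end, ts + 3602)),
                       c(0.13e-3, 0.13e-3, 1.3e-3, 1.3e-3,
                         0.13e-3, 0.13e-3))),
    ph_shift = list(
      H_o = pwlCourse(c(0, ts, ts + 1, ts + 3600, ts + 3601,
                        max(t_end, ts + 3602)),
                      10^-c(5.7, 5.7, 5.1, 5.1, 5.7, 5.7))),
    raba4d = list(
      fusion_scale = pwlCourse(span, c(0.01, 0.01))),
    viscosity_ramp = list(
      Osm_o = pwlCourse(span, rep(.osmOtherFor(pv, 0.18), 2L)),
      eta_eq = pwlCourse(
        c(0, 6000, 8000, 10000, 12000, max(t_end, 12001)),
        c(25e6, 25e6, 125e6, 125e6, 225e6, 225e6))),
    oil_injection = list(
      # increments over the resting cellular osmolyte pool, so the resting
      # total cellular osmolarity plays the role of the 0.5 M baseline
      Osm_i = pwlCourse(
        c(0, ts, ts + 1000, ts + 1001, ts + 3600, ts + 4600, ts + 4601,
          max(t_end, ts + 4602)),
        pv[["Osm_i"]] + c(0, 0, 0.25, 0, 0, 0.5, 0, 0))),
    osmolarity_sweep = list(
      Osm_o = pwlCourse(span,
        rep(.osmOtherFor(pv, overrides$Osm_total %||% 0.36), 2L))),
    viscosity_sweep = list(
      Osm_o = pwlCourse(span, rep(.osmOtherFor(pv, 0.18), 2L)),
      eta_eq = pwlCourse(span, rep(overrides$eta_eq %||% 125e6, 2L)))
  )
  if (name %in% c("osmolarity_sweep", "viscosity_sweep") &&
      !is.null(overrides$eta_eq)) {
    params <- setParams(params, eta_eq = overrides$eta_eq)
    pv <- param(params)
    if (is.null(courses$eta_eq))
      courses$eta_eq <- pwlCourse(span, rep(overrides$eta_eq, 2L))
  }
  courses <- lapply(courses, .clipCourse, span = span)
  protocol <- do.call(scenarioProtocol,
                      c(list(span = span, params = params), courses))
  list(params = params, protocol = protocol, t_end = t_end)
}

`%||%` <- function(a, b) if (is.null(a)) b else a


# Truncate a course to the simulation span, interpolating the end value,
# so short runs of long-schedule scenarios stay valid.
.clipCourse <- function(course, span) {
  if (nrow(course) == 1L) return(course)
  if (course[nrow(course), 1L] <= span[2L]) return(course)
  keep <- course[, 1L] < span[2L]
  endv <- stats::approx(course[, 1L], course[, 2L], xout = span[2L],
                        rule = 2)$y
  pwlCourse(c(course[keep, 1L], span[2L]), c(course[keep, 2L], endv))
}
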