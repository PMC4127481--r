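#' @import methods
NULL

#' Model parameter set
#'
#' Holds the complete, validated parameter vector of the growth model in
#' strict SI units (Pa, m, s; concentrations in M) together with the
#' physical constants. Construct with [defaultParams()], [calibratedParams()]
#' or [loadConfig()]; never fill slots by hand.
#'
#' @slot values Named numeric vector of model parameters (SI units).
#' @slot constants List with `R`, `T`, `F`, `Vref` from [physicalConstants()].
#' @seealso [paramTable()] for names, units and admissible ranges.
#' @export
setClass("ModelParams",
         representation(values = "numeric", constants = "list"))

setValidity("ModelParams", function(object) {
  tab <- paramTable()
  v <- object@values
  missing <- setdiff(tab$name, names(v))
  if (length(missing))
    return(paste("missing parameters:", paste(missing, collapse = ", ")))
  unknown <- setdiff(names(v), tab$name)
  if (length(unknown))
    return(paste("unknown parameters:", paste(unknown, collapse = ", ")))
  if (any(!is.finite(v))) {
    return(paste("non-finite parameters:",
                 paste(names(v)[!is.finite(v)], collapse = ", ")))
  }
  v <- v[tab$name]
  bad <- which(v < tab$lower | v > tab$upper)
  if (length(bad)) {
    return(paste0("parameter out of admissible range: ",
                  paste(sprintf("%s = %g (allowed [%g, %g])", tab$name[bad],
                                v[bad], tab$lower[bad], tab$upper[bad]),
                        collapse = "; ")))
  }
  cst <- object@constants
  need <- c("R", "T", "F", "Vref")
  if (!all(need %in% names(cst)))
    return("constants must contain R, T, F, Vref")
  if (any(unlist(cst[need]) <= 0)) return("constants must be positive")
  if (abs(cst$Vref - cst$R * cst$T / cst$F) > 1e-12 * cst$Vref)
    return("Vref must equal R*T/F")
  if (v["h0"] >= v["r0"]) return("h0 must be smaller than r0")
  TRUE
})

#' Scenario protocol: externally controlled time courses
#'
#' A set of named piecewise-linear functions of time describing everything
#' the experimenter (or the scenario) controls: the four media ion
#' concentrations, the media non-ionic osmolyte, the equilibrium wall
#' viscosity, the cellular non-ionic osmolyte, the vesicle fusion-rate scale
#' and the outer radius. Build with [scenarioProtocol()] or [buildScenario()];
#' query with [protocolAt()].
#'
#' @slot courses Named list of two-column matrices `cbind(time, value)` with
#'   strictly increasing times; one per controlled quantity.
#' @slot span Numeric length-2: the common time span covered by all courses.
#' @export
setClass("ScenarioProtocol",
         representation(courses = "list", span = "numeric"))

setValidity("ScenarioProtocol", function(object) {
  need <- .protocolCourseNames()
  if (!all(need %in% names(object@courses)))
    return(paste("protocol must define courses:",
                 paste(setdiff(need, names(object@courses)), collapse = ", ")))
  for (nm in names(object@courses)) {
    m <- object@courses[[nm]]
    if (!is.matrix(m) || ncol(m) != 2L || nrow(m) < 1L)
      return(sprintf("course '%s' must be a 2-column matrix", nm))
    if (any(!is.finite(m))) return(sprintf("course '%s' has non-finite entries", nm))
    if (nrow(m) > 1L && any(diff(m[, 1L]) <= 0))
      return(sprintf("course '%s' breakpoints must be strictly increasing", nm))
    if (nm != "eta_eq" && any(m[, 2L] < 0))
      return(sprintf("course '%s' must be non-negative", nm))
    if (nm %in% c("r", "eta_eq") && any(m[, 2L] <= 0))
      return(sprintf("course '%s' must be strictly positive", nm))
  }
  if (length(object@span) != 2L || object@span[2L] <= object@span[1L])
    return("span must be an increasing length-2 numeric")
  TRUE
})

#' Simulated trajectory
#'
#' Dense time series of the full cell state plus the derived fluxes
#' (osmotic inflow, turgor outflow, net water flux, wall-chamber rate,
#' growth rate, transporter currents, osmotic pressures, extensibility).
#' Returned by [runSimulation()]; the `data` slot is a plain data.frame with
#' one row per sample and documented column names.
#'
#' @slot data data.frame of state and derived columns (SI units plus
#'   convenience columns in \eqn{\mu m} / min scales).
#' @slot params The [ModelParams-class] used.
#' @slot protocol The [ScenarioProtocol-class] used.
#' @slot solver List of solver settings actually applied.
#' @export
setClass("Trajectory",
         representation(data = "data.frame", params = "ModelParams",
                        protocol = "ScenarioProtocol", solver = "list"))

setValidity("Trajectory", function(object) {
  d <- object@data
  if (!"time" %in% names(d)) return("data must have a 'time' column")
  if (nrow(d) > 1L && any(diff(d$time) <= 0))
    return("time grid must be strictly increasing")
  TRUE
})

#' Oscillation summary for one variable
#'
#' @slot variable Name of the analysed series.
#' @slot oscillatory Logical flag; when `FALSE` the remaining fields are `NA`.
#' @slot period Oscillation period in s (large-peak to large-peak for
#'   alternating large/small waveforms).
#' @slot amplitude Peak-to-peak amplitude over one exact period.
#' @slot baseline Mean over one exact period.
#' @slot n_cycles Number of cycles used.
#' @slot classification `"simple"` or `"large-small"` peak pattern.
#' @slot peaks Times of the (large-)peak maxima used.
#' @export
setClass("OscillationSummary",
         representation(variable = "character", oscillatory = "logical",
                        period = "numeric", amplitude = "numeric",
                        baseline = "numeric", n_cycles = "integer",
                        classification = "character", peaks = "numeric"))

#' Regulation-coefficient report for a pair of oscillatory states
#'
#' Water-side (additive) and wall-side (logarithmic) regulation coefficients
#' comparing two oscillatory growth states O1 and O2, with their sum checks
#' and the period-averaged terms used, kept for audit.
#'
#' @slot water Named numeric: `R_pi_i_w`, `R_pi_o_w`, `R_P_w`, `water_sum`.
#' @slot wall Named numeric: `R_phi_c`, `R_P_c`, `R_O_c`, `wall_sum`.
#' @slot averages data.frame of the averaged terms per state.
#' @slot windows List with the exact-period windows used per state.
#' @slot labels Character length-2 naming O1 and O2.
#' @export
setClass("RegulationReport",
         representation(water = "numeric", wall = "numeric",
                        averages = "data.frame", windows = "list",
                        labels = "character"))

#' Calibration result
#'
#' @slot best The best [ModelParams-class] found.
#' @slot objective Objective value of the best candidate.
#' @slot residuals Named numeric per-target residuals of the best candidate.
#' @slot hard_ok Logical: all hard constraints satisfied by the best candidate.
#' @slot seed The search seed.
#' @slot log data.frame iteration log (candidate id, stage, objective).
#' @export
setClass("CalibrationResult",
         representation(best = "ModelParams", objective = "numeric",
                        residuals = "numeric", hard_ok = "logical",
                        seed = "numeric", log = "data.frame"))
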