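#' Parameter catalogue
#'
#' One row per model parameter: internal (SI) name, default value, admissible
#' range, SI unit, the unit accepted in user-facing config files, and the
#' factor converting the user unit to SI. Voltage-gated transporters follow
#' the numbering of the four-ion balance: vg1 = inward-rectifier K+ channel,
#' vg2 = outward-rectifier K+ channel, vg3 = voltage-gated Ca2+ channel,
#' vg4 = plasma-membrane H+ pump, vg5 = Cl-/2H+ symporter, vg6 =
#' depolarisation-activated anion (Cl-) channel. GHK-kernel conductances are
#' per molar (A m-2 V-1 M-1) because the constant-field bracket carries the
#' concentration.
#'
#' @return data.frame with columns `name`, `default`, `lower`, `upper`,
#'   `si`, `user`, `scale`.
#' @export
paramTable <- function() {
  p <- function(name, default, lower, upper, si, user = si, scale = 1)
    data.frame(name = name, default = default, lower = lower, upper = upper,
               si = si, user = user, scale = scale,
               stringsAsFactors = FALSE)
  rbind(
    ## -- hydrodynamics ------------------------------------------------------
    p("Lp",      1e-12, 1e-14, 1e-10, "m s-1 Pa-1", "m s-1 MPa-1", 1e-6),
    p("A_osm",   1.99e-11, 1e-13, 1e-9,  "m2", "um2", 1e-12),
    p("eps",     6e6, 1e4,   1e9,   "Pa", "MPa", 1e6),
    p("Pc",      2.0e5, 0,     2e6,   "Pa", "MPa", 1e6),
    p("v_ext",   7.85e-15, 1e-18, 1e-12, "m3", "um3", 1e-18),
    ## -- cell wall ----------------------------------------------------------
    p("eta_eq",  2.5e7, 1e4,   1e10,  "Pa s", "MPa s", 1e6),
    p("k1",      0.32,  1e-5,  1e2,   "s-1"),
    p("k2a",     2.15e-14, 0,    1e-10, "m3 M-1 s-1"),
    p("fusion_scale", 1, 0,    1e3,   "1"),
    ## -- geometry -----------------------------------------------------------
    p("r0",      5e-6,  1e-7,  1e-4,  "m", "um", 1e-6),
    p("h0",      3e-7,  1e-9,  5e-6,  "m", "um", 1e-6),
    p("L0",      5e-4,  1e-6,  1e-1,  "m", "um", 1e-6),
    ## -- osmolytes and media reference --------------------------------------
    p("Osm_i",   0.299,  0,     3,     "M"),
    p("Ca_o_ref", 1e-3, 0,     1,     "M", "mM", 1e-3),
    p("H_o_ref", 10^-5.7, 0,   1,     "M"),
    p("K_o_ref", 1e-3,  0,     1,     "M", "mM", 1e-3),
    p("Cl_o_ref", 3e-3, 0,     1,     "M", "mM", 1e-3),
    p("Osm_o_ref", 0.354998, 0, 3,    "M", "Osm", 1),
    ## -- membrane -----------------------------------------------------------
    p("Cm",      0.01,  1e-4,  1,     "F m-2"),
    p("ov_scale", 1,    1e-3,  1e3,   "1"),
    ## -- voltage-gated transporter kernels -----------------------------------
    p("g_vg1",   100,   0,     1e6,   "A m-2 V-1 M-1"),
    p("Vh_vg1", -0.125, -0.5,   0.2,   "V"),
    p("s_vg1",   0.012, 1e-3,  0.2,   "V"),
    p("g_vg2",   1100,   0,     1e6,   "A m-2 V-1 M-1"),
    p("Vh_vg2", -0.095, -0.5,   0.2,   "V"),
    p("s_vg2",   0.010, 1e-3,  0.2,   "V"),
    p("g_vg3",   1200,    0,     1e6,   "A m-2 V-1 M-1"),
    p("Vh_vg3", -0.105, -0.5,   0.2,   "V"),
    p("s_vg3",   0.008, 1e-3,  0.2,   "V"),
    p("I_pump_max", 0.085, 0,    1e3,   "A m-2"),
    p("Vh_pump", -0.15, -0.6,  0.2,   "V"),
    p("s_pump",  0.05,  1e-3,  0.2,   "V"),
    p("Km_pump", 1e-7,  1e-10, 1e-2,  "M"),
    p("g_vg5",   0.1,   0,     1e4,   "S m-2"),
    p("Vh_vg5", -0.10, -0.5,   0.2,   "V"),
    p("s_vg5",   0.02,  1e-3,  0.2,   "V"),
    p("g_vg6",   50,   0,     1e6,   "A m-2 V-1 M-1"),
    p("Vh_vg6", -0.08, -0.5,   0.2,   "V"),
    p("s_vg6",   0.010, 1e-3,  0.2,   "V"),
    ## -- stretch-activated channels ------------------------------------------
    p("g_Ca_sa", 200,  0,     1e7,   "A m-2 V-1 M-1"),
    p("g_K_sa",  200,  0,     1e7,   "A m-2 V-1 M-1"),
    p("g_Cl_sa", 0,     0,     1e7,   "A m-2 V-1 M-1"),
    p("kOC0",    2.0,   1e-6,  1e3,   "s-1"),
    p("kCO0",    2.3557e-19, 1e-300, 1e3,  "s-1"),
    p("ka",      2e-4,  0,     1e-2,  "Pa-1"),
    ## -- ion relaxation to shank set-points ----------------------------------
    p("k_relax_Ca", 2.8,   0,   1e6,   "s-1"),
    p("k_relax_H",  3e4,  0,   1e6,   "s-1"),
    p("k_relax_K",  2e-2, 0,   1e4,   "s-1"),
    p("k_relax_Cl", 2e-2, 0,   1e4,   "s-1"),
    p("setpoint_Ca", 2e-7, 0,  1,     "M"),
    p("setpoint_H",  1e-7, 0,  1,     "M"),
    p("setpoint_K",  0.2, 0,  3,     "M"),
    p("setpoint_Cl", 0.06, 0,  3,     "M"),
    p("buffer_Ca", 0,    0,    1e6,   "1"),
    p("buffer_H",  0,    0,    1e6,   "1"),
    ## -- slow activation of the outward-rectifier K+ channel -----------------
    p("tau_n",   28.5,    1e-2,  1e3,   "s")
  )
}

#' Default (uncalibrated) parameter set
#'
#' The catalogue defaults in SI units. These are a plausible starting point,
#' not the shipped calibrated set: use [calibratedParams()] for simulations
#' meant to reproduce the reference oscillatory behaviour.
#'
#' @param constants Output of [physicalConstants()].
#' @return A [ModelParams-class] object.
#' @export
defaultParams <- function(constants = physicalConstants()) {
  tab <- paramTable()
  v <- stats::setNames(tab$default, tab$name)
  new("ModelParams", values = v, constants = constants)
}

#' Shipped calibrated parameter set
#'
#' Loads the parameter file shipped with the package, the result of the
#' seeded calibration against the experimental constraints (isotonic period
#' about 50 s, growth rate about 4 um/min, mean turgor in 0.1-0.4 MPa,
#' turgor oscillation amplitude below the 0.005 MPa detection limit).
#'
#' @return A [ModelParams-class] object.
#' @export
calibratedParams <- function() {
  path <- system.file("extdata", "calibrated_params.yaml",
                      package = "pollentube", mustWork = TRUE)
  loadConfig(path)$params
}

#' Read one or more parameter values
#'
#' @param params A [ModelParams-class] object.
#' @param name Parameter name(s); omit for the full named vector.
#' @return Named numeric vector (SI units).
#' @export
param <- function(params, name = NULL) {
  stopifnot(is(params, "ModelParams"))
  if (is.null(name)) return(params@values)
  bad <- setdiff(name, names(params@values))
  if (length(bad))
    stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  params@values[name]
}

#' Modify parameters, revalidating the result
#'
#' @param params A [ModelParams-class] object.
#' @param ... Named scalar replacements in SI units, or a single named
#'   numeric vector.
#' @return A new validated [ModelParams-class] object.
#' @examples
#' p <- defaultParams()
#' p2 <- setParams(p, eta_eq = 125e6, Pc = 0.19e6)
#' @export
setParams <- function(params, ...) {
  stopifnot(is(params, "ModelParams"))
  repl <- list(...)
  if (!length(repl)) return(params)
  if (length(repl) == 1L && is.null(names(repl)) ||
      (length(repl) == 1L && is.numeric(repl[[1L]]) &&
       length(repl[[1L]]) > 1L)) {
    repl <- as.list(repl[[1L]])
  }
  if (is.null(names(repl)) || any(names(repl) == ""))
    stop("replacements must be named")
  v <- params@values
  bad <- setdiff(names(repl), names(v))
  if (length(bad))
    stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  v[names(repl)] <- vapply(repl, as.numeric, numeric(1L))
  out <- new("ModelParams", values = v, constants = params@constants)
  validObject(out)
  out
}

# Parameter vector in the fixed order expected by the compiled RHS,
# with the physical constants prepended.
.packParams <- function(params) {
  cst <- params@constants
  v <- params@values[paramTable()$name]
  c(R = cst$R, T = cst$T, F = cst$F, Vref = cst$Vref, v)
}
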