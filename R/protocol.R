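.protocolCourseNames <- function() {
  c("Ca_o", "H_o", "K_o", "Cl_o", "Osm_o", "eta_eq", "Osm_i",
    "fusion_scale", "r")
}

#' Build a piecewise-linear time course
#'
#' @param time Breakpoint times (s), strictly increasing.
#' @param value Values at the breakpoints.
#' @return A two-column matrix usable as a protocol course.
#' @export
pwlCourse <- function(time, value) {
  stopifnot(length(time) == length(value), length(time) >= 1L,
            all(is.finite(time)), all(is.finite(value)))
  if (length(time) > 1L && any(diff(time) <= 0))
    stop("breakpoint times must be strictly increasing")
  cbind(time = as.numeric(time), value = as.numeric(value))
}

# A step change at time t0, encoded as a linear ramp of the given width so
# the right-hand side stays continuous for the solver.
.stepCourse <- function(before, after, t0, span, ramp = 1) {
  end <- max(span[2L], t0 + ramp + 1)
  pwlCourse(c(span[1L], t0, t0 + ramp, end),
            c(before, before, after, after))
}

#' Assemble a scenario protocol
#'
#' Any course not supplied is held constant at its reference value taken from
#' `params` (media composition, equilibrium viscosity, cellular non-ionic
#' osmolyte, fusion-rate scale 1, radius `r0`).
#'
#' @param span Length-2 numeric, the simulation time span (s).
#' @param params A [ModelParams-class] supplying reference values.
#' @param ... Named courses built with [pwlCourse()]; names among
#'   `Ca_o`, `H_o`, `K_o`, `Cl_o`, `Osm_o` (M), `eta_eq` (Pa s), `Osm_i` (M),
#'   `fusion_scale` (1), `r` (m).
#' @return A [ScenarioProtocol-class] object.
#' @examples
#' p <- defaultParams()
#' prot <- scenarioProtocol(c(0, 7200), p,
#'   eta_eq = pwlCourse(c(0, 6000, 7200), c(25e6, 25e6, 125e6)))
#' @export
scenarioProtocol <- function(span, params, ...) {
  stopifnot(length(span) == 2L, span[2L] > span[1L])
  supplied <- list(...)
  bad <- setdiff(names(supplied), .protocolCourseNames())
  if (length(bad))
    stop("unknown protocol course(s): ", paste(bad, collapse = ", "))
  v <- param(params)
  ref <- list(Ca_o = v[["Ca_o_ref"]], H_o = v[["H_o_ref"]],
              K_o = v[["K_o_ref"]], Cl_o = v[["Cl_o_ref"]],
              Osm_o = v[["Osm_o_ref"]], eta_eq = v[["eta_eq"]],
              Osm_i = v[["Osm_i"]], fusion_scale = v[["fusion_scale"]],
              r = v[["r0"]])
  courses <- lapply(.protocolCourseNames(), function(nm) {
    if (nm %in% names(supplied)) supplied[[nm]]
    else pwlCourse(span, rep(ref[[nm]], 2L))
  })
  names(courses) <- .protocolCourseNames()
  out <- new("ScenarioProtocol", courses = courses, span = as.numeric(span))
  validObject(out)
  out
}

# Linear interpolation with constant extension of the end values (the
# validity range check lives in protocolAt).
.courseAt <- function(course, t) {
  if (nrow(course) == 1L) return(rep(course[1L, 2L], length(t)))
  stats::approx(course[, 1L], course[, 2L], xout = t, rule = 2)$y
}

.courseSlopeAt <- function(course, t) {
  if (nrow(course) == 1L) return(rep(0, length(t)))
  tt <- course[, 1L]; vv <- course[, 2L]
  slopes <- diff(vv) / diff(tt)
  # active segment: the one whose half-open interval [t_k, t_{k+1}) holds t
  idx <- findInterval(t, tt, rightmost.closed = FALSE, all.inside = TRUE)
  out <- slopes[idx]
  # outside the course the value is held constant, so the slope is zero;
  # at the final breakpoint the last segment is still the active one
  out[t < tt[1L] | t > tt[length(tt)]] <- 0
  out
}

#' Evaluate a protocol at a time point
#'
#' Piecewise-linear interpolation of every controlled course, plus the slope
#' `drdt` of the active radius segment.
#'
#' @param protocol A [ScenarioProtocol-class] object.
#' @param t Time (s), scalar, within the protocol span.
#' @return Named list of the controlled quantities at `t` and `drdt`.
#' @export
protocolAt <- function(protocol, t) {
  stopifnot(is(protocol, "ScenarioProtocol"), length(t) == 1L, is.finite(t))
  sp <- protocol@span
  if (t < sp[1L] || t > sp[2L])
    stop(sprintf("t = %g outside protocol span [%g, %g]", t, sp[1L], sp[2L]))
  out <- lapply(protocol@courses, .courseAt, t = t)
  out$drdt <- .courseSlopeAt(protocol@courses$r, t)
  out
}

# Breakpoint times of all courses within the span (used as forced solver
# restart points).
.protocolBreaks <- function(protocol) {
  b <- sort(unique(unlist(lapply(protocol@courses, function(m) m[, 1L]))))
  b[b > protocol@span[1L] & b < protocol@span[2L]]
}

# Forcing matrices in the fixed order expected by the compiled model.
.protocolForcings <- function(protocol) {
  cs <- protocol@courses
  r <- cs$r
  # dr/dt as a forcing: piecewise-constant slopes, encoded with narrow (1 s)
  # linear transitions at interior breakpoints.
  if (nrow(r) == 1L) {
    drdt <- cbind(protocol@span, c(0, 0))
  } else {
    tt <- r[, 1L]
    slopes <- c(diff(r[, 2L]) / diff(tt))
    n <- length(slopes)
    times <- c(tt[1L])
    vals <- c(slopes[1L])
    if (n > 1L) {
      for (k in 2L:n) {
        w <- min(1, (tt[k + 1L] - tt[k]) / 2, (tt[k] - tt[k - 1L]) / 2)
        times <- c(times, tt[k] - w, tt[k] + w)
        vals <- c(vals, slopes[k - 1L], slopes[k])
      }
    }
    times <- c(times, tt[n + 1L])
    vals <- c(vals, slopes[n])
    drdt <- cbind(times, vals)
  }
  c(unname(cs[.protocolCourseNames()]), list(drdt))
}
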