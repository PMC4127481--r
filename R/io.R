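#' Write a trajectory to CSV with a JSON metadata sidecar
#'
#' One row per sample. With `header_comment = TRUE` the CSV starts with `#`
#' lines documenting the column units; disable for strict-CSV consumers.
#' The sidecar `<path>.meta.json` records parameters, protocol breakpoints,
#' solver settings and a config hash.
#'
#' @param traj A [Trajectory-class] object.
#' @param path Output CSV path.
#' @param header_comment Write the unit header comment lines.
#' @return `path`, invisibly.
#' @export
writeTrajectory <- function(traj, path, header_comment = TRUE) {
  d <- trajectoryData(traj)
  con <- file(path, "w")
  on.exit(close(con))
  if (header_comment) {
    writeLines(c(
      "# pollentube trajectory; SI units unless suffixed",
      "# time [s]; v [m3]; P [Pa]; L [m]; eta [Pa s]; h [m]; ions [M];",
      "# V [volt]; fluxes [m3 s-1]; currents [A m-2]; pressures [Pa];",
      "# growth_um_min [um min-1]; volume_change_um3_s [um3 s-1]"), con)
  }
  utils::write.csv(d, con, row.names = FALSE)
  meta <- list(
    parameters = as.list(traj@params@values),
    constants = traj@params@constants,
    solver = traj@solver,
    protocol = lapply(traj@protocol@courses, function(m)
      list(time = m[, 1L], value = m[, 2L])),
    span = traj@protocol@span,
    config_hash = configHash(traj@params),
    n_samples = nrow(d))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Stable hash of a parameter set
#'
#' A short hex digest over the full-precision parameter values, used to tag
#' outputs; identical configurations give identical hashes.
#'
#' @param params A [ModelParams-class] object.
#' @return Character scalar.
#' @export
configHash <- function(params) {
  s <- paste(names(params@values),
             sprintf("%.17g", params@values), collapse = ";")
  # polynomial rolling hash mod a Mersenne prime: stable, dependency-free
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 131 + ch) %% 2147483647
  sprintf("%08x", h)
}

#' Write an oscillation summary as JSON
#'
#' @param summaries A named list of [OscillationSummary-class] objects (or a
#'   single one).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeOscillationSummary <- function(summaries, path) {
  if (is(summaries, "OscillationSummary")) summaries <- list(summaries)
  out <- lapply(summaries, function(s) list(
    variable = s@variable, oscillatory = s@oscillatory, period_s = s@period,
    amplitude = s@amplitude, baseline = s@baseline, n_cycles = s@n_cycles,
    classification = s@classification))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a regulation report as JSON
#'
#' @param report A [RegulationReport-class] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeRegulationReport <- function(report, path) {
  stopifnot(is(report, "RegulationReport"))
  out <- list(states = report@labels,
              water = as.list(report@water), wall = as.list(report@wall),
              windows = report@windows,
              averaged_terms = report@averages)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
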