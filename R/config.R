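#' Load a model configuration file
#'
#' Reads a structured YAML or JSON configuration with optional sections
#' `constants`, `parameters`, `protocol`, `solver`, `analysis` and `init`.
#' Unspecified entries take the documented defaults. Parameter values are
#' given either in SI units (`units: SI`, the form written by
#' [writeConfig()]) or in the user-facing units of [paramTable()]
#' (`units: user`, the default for hand-written files: MPa, \eqn{\mu m},
#' mM, Osm where applicable).
#'
#' Protocol courses are given as `{course: {time: [...], value: [...]}}` in
#' SI units, or via `scenario: <name>` to use a named scenario from
#' [buildScenario()].
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file.
#' @return List with elements `params` ([ModelParams-class]), `protocol`
#'   ([ScenarioProtocol-class] or `NULL`), `solver`, `analysis` and `init`
#'   (named state vector or `NULL`).
#' @export
loadConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  cfg <- switch(ext,
    yaml = , yml = yaml::read_yaml(path),
    json = jsonlite::fromJSON(path, simplifyVector = TRUE),
    stop("unsupported config extension '.", ext, "' (use yaml or json)"))
  if (!is.list(cfg)) stop("config must be a mapping")

  cst <- physicalConstants()
  if (!is.null(cfg$constants$temperature))
    cst <- physicalConstants(cfg$constants$temperature)

  tab <- paramTable()
  vals <- stats::setNames(tab$default, tab$name)
  units <- cfg$units %||% "user"
  if (!units %in% c("user", "SI"))
    stop("config field 'units' must be 'user' or 'SI'")
  if (!is.null(cfg$parameters)) {
    pv <- cfg$parameters
    if (is.null(names(pv)) || any(names(pv) == ""))
      stop("config error: 'parameters' entries must be named")
    bad <- setdiff(names(pv), tab$name)
    if (length(bad))
      stop("config error: unknown parameter(s): ",
           paste(bad, collapse = ", "))
    for (nm in names(pv)) {
      x <- pv[[nm]]
      if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
        stop("config error: parameter '", nm, "' must be a finite number")
      sc <- if (units == "user") tab$scale[tab$name == nm] else 1
      vals[nm] <- x * sc
    }
  }
  params <- new("ModelParams", values = vals, constants = cst)
  validObject(params)

  protocol <- NULL
  if (!is.null(cfg$protocol)) {
    pr <- cfg$protocol
    if (!is.null(pr$scenario)) {
      protocol <- buildScenario(pr$scenario, params = params,
                                t_end = pr$t_end)$protocol
    } else {
      span <- as.numeric(pr$span %||% c(0, 7200))
      courses <- pr$courses %||% list()
      built <- lapply(courses, function(co)
        pwlCourse(as.numeric(co$time), as.numeric(co$value)))
      protocol <- do.call(scenarioProtocol,
                          c(list(span = span, params = params), built))
    }
  }

  solver <- do.call(solverSettings, cfg$solver %||% list())
  init <- NULL
  if (!is.null(cfg$init)) {
    init <- unlist(cfg$init)
    miss <- setdiff(.stateNames(), names(init))
    if (length(miss))
      stop("config error: init missing state component(s): ",
           paste(miss, collapse = ", "))
    init <- init[.stateNames()]
  }
  list(params = params, protocol = protocol, solver = solver,
       analysis = cfg$analysis %||% list(), init = init)
}

#' Write a configuration file
#'
#' Serialises a parameter set (and optionally an initial state and solver
#' settings) in SI units. A file written here and read back with
#' [loadConfig()] reproduces every value bit-identically.
#'
#' @param params A [ModelParams-class] object.
#' @param path Output path (`.yaml`/`.yml` or `.json`).
#' @param init Optional named state vector stored under `init`.
#' @param solver Optional solver settings list.
#' @return `path`, invisibly.
#' @export
writeConfig <- function(params, path, init = NULL, solver = NULL) {
  stopifnot(is(params, "ModelParams"))
  cfg <- list(
    units = "SI",
    constants = list(temperature = params@constants$T),
    parameters = as.list(params@values))
  if (!is.null(init)) cfg$init <- as.list(init[.stateNames()])
  if (!is.null(solver)) cfg$solver <- solver[c("rtol", "sample_dt", "method")]
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    # force 17 significant digits so a write/read round-trip is
    # bit-identical (the default yaml precision is lossy)
    verb <- function(x) {
      if (is.list(x)) return(lapply(x, verb))
      if (is.numeric(x))
        return(structure(sprintf("%.17g", x), class = "verbatim"))
      x
    }
    yaml::write_yaml(verb(cfg), path)
  } else if (ext == "json") {
    # I(17) = 17 significant digits: bit-identical double round-trip
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = I(17),
                         pretty = TRUE)
  } else stop("unsupported config extension '.", ext, "'")
  invisible(path)
}
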