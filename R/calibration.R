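#' Calibration target set
#'
#' Experimental constraints the calibrated model must satisfy in isotonic
#' (0.36 Osm) growth: the oscillation period, the growth-rate band, the
#' admissible mean turgor window and the turgor-oscillation detectability
#' ceiling. Period and growth rate are soft least-squares terms; the turgor
#' band, the amplitude ceiling and the existence of an oscillation are hard
#' constraints.
#'
#' @param period_s Target oscillation period (s) and `period_tol_s` its
#'   tolerance unit.
#' @param growth_um_min Target growth rate and `growth_tol_um_min` its
#'   tolerance unit.
#' @param turgor_band_MPa Hard admissible window for the cycle-mean turgor.
#' @param turgor_amp_max_MPa Hard ceiling for the turgor peak-to-peak
#'   amplitude (experimental resolution limit).
#' @param t_end Isotonic run length used for evaluation (s).
#' @return List of targets for [calibrationObjective()] / [calibrate()].
#' @export
calibrationTargets <- function(period_s = 50, period_tol_s = 5,
                               growth_um_min = 4.07,
                               growth_tol_um_min = 0.36,
                               turgor_band_MPa = c(0.1, 0.4),
                               turgor_amp_max_MPa = 0.005,
                               t_end = 3600) {
  stopifnot(period_tol_s > 0, growth_tol_um_min > 0,
            turgor_band_MPa[2L] > turgor_band_MPa[1L],
            turgor_amp_max_MPa > 0)
  list(period_s = period_s, period_tol_s = period_tol_s,
       growth_um_min = growth_um_min, growth_tol_um_min = growth_tol_um_min,
       turgor_band_MPa = turgor_band_MPa,
       turgor_amp_max_MPa = turgor_amp_max_MPa, t_end = t_end)
}

# Large finite penalty for non-oscillatory or failed runs; exceeds any
# achievable residual sum of an oscillatory candidate in the search box.
.CAL_PENALTY <- 1e6

#' Isotonic growth metrics of a parameter set
#'
#' Runs the isotonic scenario and extracts the metrics used by the
#' calibration objective.
#'
#' @param params A [ModelParams-class] object.
#' @param t_end Run length (s).
#' @param init Optional initial state (default cold start).
#' @param sample_dt Output sampling interval (s).
#' @return List: `oscillatory`, `period_s`, `growth_um_min` (cycle-mean),
#'   `turgor_MPa` (cycle-mean), `turgor_amp_MPa` (peak-to-peak).
#' @export
isotonicMetrics <- function(params, t_end = 3600, init = NULL,
                            sample_dt = 0.25) {
  sc <- buildScenario("isotonic", params = params, t_end = t_end)
  traj <- runSimulation(sc$params, sc$protocol, init = init,
                        solver = solverSettings(sample_dt = sample_dt))
  osc <- oscillationOf(traj, "growth_um_min")
  if (!osc@oscillatory)
    return(list(oscillatory = FALSE, period_s = NA_real_,
                growth_um_min = NA_real_, turgor_MPa = NA_real_,
                turgor_amp_MPa = NA_real_))
  win <- exactPeriodWindow(osc)
  d <- trajectoryData(traj)
  inwin <- d$time >= win[1L] & d$time < win[2L]
  list(oscillatory = TRUE, period_s = osc@period,
       growth_um_min = periodAverage(d$time, d$growth_um_min, win),
       turgor_MPa = periodAverage(d$time, d$P_MPa, win),
       turgor_amp_MPa = diff(range(d$P_MPa[inwin])))
}

#' Calibration objective
#'
#' Weighted sum of squared normalised residuals of the soft targets, plus
#' a large finite penalty (1e6) for runs that fail to integrate, fail to
#' oscillate, or violate a hard constraint. A candidate meeting every target
#' exactly scores 0; a period off by one tolerance unit contributes exactly
#' 1.
#'
#' @param params A [ModelParams-class] object.
#' @param targets From [calibrationTargets()].
#' @param init Optional initial state passed to [isotonicMetrics()].
#' @return List: `objective`, `residuals` (named), `metrics`, `hard_ok`.
#' @export
calibrationObjective <- function(params, targets = calibrationTargets(),
                                 init = NULL) {
  m <- tryCatch(
    isotonicMetrics(params, t_end = targets$t_end, init = init),
    error = function(e) {
      message("calibration candidate failed: ", conditionMessage(e))
      NULL
    })
  if (is.null(m) || !isTRUE(m$oscillatory)) {
    return(list(objective = .CAL_PENALTY,
                residuals = c(period = NA_real_, growth = NA_real_),
                metrics = m, hard_ok = FALSE))
  }
  res <- c(
    period = (m$period_s - targets$period_s) / targets$period_tol_s,
    growth = (m$growth_um_min - targets$growth_um_min) /
      targets$growth_tol_um_min)
  hard_ok <- m$turgor_MPa >= targets$turgor_band_MPa[1L] &&
    m$turgor_MPa <= targets$turgor_band_MPa[2L] &&
    m$turgor_amp_MPa < targets$turgor_amp_max_MPa
  obj <- sum(res^2) + if (hard_ok) 0 else .CAL_PENALTY
  list(objective = obj, residuals = res, metrics = m, hard_ok = hard_ok)
}

#' Seeded calibration search
#'
#' Space-filling Latin-hypercube screening over the search box (log-uniform
#' in each free parameter), followed by Nelder-Mead polish of the best
#' screening candidate in log-parameter space. Fully deterministic for a
#' fixed seed and budget.
#'
#' @param targets From [calibrationTargets()].
#' @param box Named list of `c(lower, upper)` SI bounds per free parameter.
#' @param seed Integer random seed.
#' @param budget Total number of objective evaluations (screening plus
#'   polish); `0` returns a failure report without evaluating.
#' @param base Baseline [ModelParams-class]; free parameters are replaced,
#'   the rest kept.
#' @param screen_frac Fraction of the budget spent on screening.
#' @return A [CalibrationResult-class] object.
#' @export
calibrate <- function(targets = calibrationTargets(), box, seed = 1L,
                      budget = 200L, base = defaultParams(),
                      screen_frac = 0.6) {
  stopifnot(is.list(box), length(box) >= 1L, !is.null(names(box)))
  free <- names(box)
  lower <- vapply(box, `[`, numeric(1L), 1L)
  upper <- vapply(box, `[`, numeric(1L), 2L)
  if (any(lower <= 0) || any(upper <= lower))
    stop("box bounds must be positive with upper > lower")
  mkparams <- function(x) {
    repl <- stats::setNames(as.list(exp(x)), free)
    do.call(setParams, c(list(base), repl))
  }
  log_entries <- list()
  evalx <- function(x, stage, id) {
    p <- tryCatch(mkparams(x), error = function(e) NULL)
    o <- if (is.null(p)) list(objective = .CAL_PENALTY,
                              residuals = c(period = NA, growth = NA),
                              hard_ok = FALSE)
    else calibrationObjective(p, targets)
    log_entries[[length(log_entries) + 1L]] <<-
      data.frame(id = id, stage = stage, objective = o$objective)
    o
  }

  if (budget <= 0) {
    return(new("CalibrationResult", best = base, objective = .CAL_PENALTY,
               residuals = c(period = NA_real_, growth = NA_real_),
               hard_ok = FALSE, seed = as.numeric(seed),
               log = data.frame(id = integer(0), stage = character(0),
                                objective = numeric(0))))
  }

  n_screen <- max(1L, min(budget, ceiling(budget * screen_frac)))
  set.seed(as.integer(seed))
  U <- lhs::randomLHS(n_screen, length(free))
  X <- t(log(lower) + t(U) * (log(upper) - log(lower)))

  best_x <- NULL; best <- NULL
  for (i in seq_len(n_screen)) {
    o <- evalx(X[i, ], "screen", i)
    if (is.null(best) || o$objective < best$objective) {
      best <- o; best_x <- X[i, ]
    }
  }
  n_polish <- budget - n_screen
  if (n_polish > 1L && best$objective < .CAL_PENALTY) {
    k <- n_screen
    opt <- stats::optim(best_x, function(x) {
      k <<- k + 1L
      evalx(pmin(pmax(x, log(lower)), log(upper)), "polish", k)$objective
    }, method = "Nelder-Mead",
    control = list(maxit = n_polish, warn.1d.NelderMead = FALSE))
    xo <- pmin(pmax(opt$par, log(lower)), log(upper))
    oo <- evalx(xo, "final", k + 1L)
    if (oo$objective <= best$objective) {
      best <- oo; best_x <- xo
    }
  }
  new("CalibrationResult", best = mkparams(best_x),
      objective = best$objective,
      residuals = best$residuals, hard_ok = isTRUE(best$hard_ok),
      seed = as.numeric(seed), log = do.call(rbind, log_entries))
}
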