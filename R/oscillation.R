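#' Oscillation-analysis settings
#'
#' @param tail_fraction Fraction of the series (from the end) analysed;
#'   the leading transient is discarded (default last 50 percent).
#' @param prominence_frac Peak prominence threshold as a fraction of the
#'   analysed series range (default 0.05).
#' @param large_small_ratio Alternating peaks whose smaller/larger relative
#'   height difference exceeds this ratio are classified large/small and the
#'   period is measured large-peak to large-peak (default 0.5).
#' @param amplitude_floor Relative amplitude (range over `|baseline|`, or
#'   absolute when the baseline is 0) below which the series is declared
#'   non-oscillatory (default 1e-6).
#' @return List of settings for [detectOscillation()].
#' @export
oscillationSettings <- function(tail_fraction = 0.5, prominence_frac = 0.05,
                                large_small_ratio = 0.5,
                                amplitude_floor = 1e-6) {
  list(tail_fraction = tail_fraction, prominence_frac = prominence_frac,
       large_small_ratio = large_small_ratio,
       amplitude_floor = amplitude_floor)
}

# Local maxima with a prominence criterion: height above the higher of the
# two minima separating the peak from higher ground on either side.
# Returns indices (time-ordered) and their prominences; plateaus take the
# first sample, ties break toward the earlier time.
.findPeaks <- function(x, prominence) {
  n <- length(x)
  if (n < 3L) return(list(idx = integer(0), prom = numeric(0)))
  dx <- diff(x)
  cand <- which(dx[-(n - 1L)] > 0 & dx[-1L] <= 0) + 1L
  if (!length(cand)) return(list(idx = integer(0), prom = numeric(0)))
  prom <- numeric(length(cand))
  for (j in seq_along(cand)) {
    i <- cand[j]
    left <- x[seq_len(i - 1L)]
    right <- x[seq.int(i + 1L, n)]
    hl <- which(left > x[i])
    lmin <- if (length(hl)) min(x[seq.int(max(hl) + 1L, i - 1L)]) else min(left)
    hr <- which(right > x[i])
    rmin <- if (length(hr)) min(right[seq_len(min(hr) - 1L)]) else min(right)
    prom[j] <- x[i] - max(lmin, rmin)
  }
  keep <- prom >= prominence
  list(idx = cand[keep], prom = prom[keep])
}

#' Detect and summarise an oscillation
#'
#' Finds peaks in the tail of a sampled series with a prominence threshold,
#' classifies the waveform as simple or alternating large/small, and reports
#' the period (large-peak to large-peak for alternating shapes), the
#' peak-to-peak amplitude over one exact period, and the cycle-mean
#' baseline.
#'
#' @param time,value Numeric vectors: sampling times (s) and series values,
#'   or a data.frame with columns `time`/`value` as first argument.
#' @param variable Label stored in the summary.
#' @param settings From [oscillationSettings()].
#' @return An [OscillationSummary-class] object.
#' @export
detectOscillation <- function(time, value = NULL, variable = "series",
                              settings = oscillationSettings()) {
  if (is.data.frame(time)) {
    value <- time$value; time <- time$time
  }
  stopifnot(length(time) == length(value), length(time) >= 10L)
  i0 <- max(1L, floor(length(time) * (1 - settings$tail_fraction)) + 1L)
  tt <- time[i0:length(time)]
  xx <- value[i0:length(value)]

  rng <- diff(range(xx))
  base_scale <- max(abs(mean(xx)), rng)
  non_osc <- function() new("OscillationSummary", variable = variable,
                            oscillatory = FALSE, period = NA_real_,
                            amplitude = NA_real_, baseline = mean(xx),
                            n_cycles = 0L, classification = "none",
                            peaks = numeric(0))
  if (rng <= settings$amplitude_floor * max(base_scale, .Machine$double.eps))
    return(non_osc())

  found <- .findPeaks(xx, prominence = settings$prominence_frac * rng)
  pk <- found$idx
  if (length(pk) < 4L) {
    if (length(pk) < 2L) return(non_osc())
    stop("insufficient data: fewer than 3 detected cycles")
  }

  # alternating large/small classification: if odd- and even-indexed peaks
  # form two prominence classes whose ratio falls below the threshold, the
  # period is measured large-peak to large-peak
  odd <- found$prom[seq(1L, length(pk), by = 2L)]
  even <- found$prom[seq(2L, length(pk), by = 2L)]
  lo <- min(stats::median(odd), stats::median(even))
  hi <- max(stats::median(odd), stats::median(even))
  alt <- lo / hi < settings$large_small_ratio
  classification <- "simple"
  big <- pk
  if (alt) {
    classification <- "large-small"
    big <- if (stats::median(odd) >= stats::median(even))
      pk[seq(1L, length(pk), by = 2L)] else pk[seq(2L, length(pk), by = 2L)]
  }
  if (length(big) < 4L)
    stop("insufficient data: fewer than 3 detected cycles")

  # mean spacing over all detected (large-)peaks: robust to the sampling
  # quantisation of individual peak times
  period <- (tt[big[length(big)]] - tt[big[1L]]) / (length(big) - 1L)
  # amplitude and baseline over the last exact period
  w <- c(tt[big[length(big) - 1L]], tt[big[length(big)]])
  inwin <- tt >= w[1L] & tt < w[2L]
  amplitude <- diff(range(xx[inwin]))
  baseline <- periodAverage(tt, xx, w)
  new("OscillationSummary", variable = variable, oscillatory = TRUE,
      period = period, amplitude = amplitude, baseline = baseline,
      n_cycles = length(big) - 1L, classification = classification,
      peaks = tt[big])
}

#' Exact-period averaging window
#'
#' The averaging window runs from the time a (large-)peak maximum is reached
#' to the time the next same-class maximum is reached, half-open on the
#' right.
#'
#' @param summary An oscillatory [OscillationSummary-class].
#' @param anchor Index of the anchor peak among the detected (large) peaks
#'   (default: second to last, so the window closes with a full cycle).
#' @return Numeric `c(t_start, t_end)`.
#' @export
exactPeriodWindow <- function(summary, anchor = NULL) {
  stopifnot(is(summary, "OscillationSummary"))
  if (!summary@oscillatory) stop("series is not oscillatory")
  pks <- summary@peaks
  if (is.null(anchor)) anchor <- length(pks) - 1L
  if (anchor < 1L || anchor + 1L > length(pks))
    stop("insufficient data: anchor peak has no successor")
  c(pks[anchor], pks[anchor + 1L])
}

#' Time-weighted mean over a half-open window
#'
#' Trapezoidal average of a sampled series over `[t_start, t_end)`; the end
#' point value enters only through interpolation of the final trapezoid.
#'
#' @param time,value Sampled series.
#' @param window Numeric `c(t_start, t_end)` within the series span.
#' @return The mean value.
#' @export
periodAverage <- function(time, value, window) {
  if (is.data.frame(time)) {
    value <- time$value; time <- time$time
  }
  stopifnot(length(window) == 2L, window[2L] > window[1L])
  if (window[1L] < time[1L] || window[2L] > time[length(time)])
    stop("window outside the series span")
  inside <- time > window[1L] & time < window[2L]
  tt <- c(window[1L], time[inside], window[2L])
  vv <- c(stats::approx(time, value, xout = window[1L])$y,
          value[inside],
          stats::approx(time, value, xout = window[2L])$y)
  dt <- diff(tt)
  sum(dt * (vv[-length(vv)] + vv[-1L]) / 2) / (window[2L] - window[1L])
}

#' Oscillation summary of one trajectory variable
#'
#' Convenience wrapper: extracts a column from a trajectory and runs
#' [detectOscillation()] on it.
#'
#' @param traj A [Trajectory-class] object.
#' @param var Column name (e.g. `"growth_um_min"`, `"P"`).
#' @param from,to Time window to analyse (default: full span, of which the
#'   tail fraction in `settings` is used).
#' @param settings From [oscillationSettings()].
#' @return An [OscillationSummary-class] object.
#' @export
oscillationOf <- function(traj, var, from = -Inf, to = Inf,
                          settings = oscillationSettings()) {
  s <- trajectorySeries(traj, var, from, to)
  detectOscillation(s$time, s$value, variable = var, settings = settings)
}
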