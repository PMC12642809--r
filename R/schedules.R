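#' Dose schedules: inlet concentration as a function of time
#'
#' A dose schedule specifies the inlet (or loading) concentration of a
#' chemical for all t >= 0. Because the transport model is linear in
#' concentration, schedule units are arbitrary as long as they are used
#' consistently; every simulated concentration scales with the schedule
#' amplitude.
#'
#' Four variants are provided:
#' * `schedule_constant(c0)` — constant level.
#' * `schedule_pulse(c0, t_on, t_off)` — square pulse, `c0` on
#'   `[t_on, t_off)` and 0 elsewhere.
#' * `schedule_periodic(mean, amplitudes, phases, period)` — truncated
#'   Fourier series `mean + sum_k amplitudes[k] * cos(2*pi*k*(t - phases[k]) / period)`,
#'   clipped at zero (with a warning) if the harmonics drive it negative.
#' * `schedule_tabulated(times, concentrations, rule)` — interpolation of a
#'   table, linear (default) or constant (left-continuous step).
#'
#' @param c0,mean Concentration levels (>= 0).
#' @param t_on,t_off Pulse start and end times, h (`t_off > t_on >= 0`).
#' @param amplitudes Numeric vector of harmonic amplitudes (k = 1, 2, ...).
#' @param phases Numeric vector of per-harmonic phase times (h), recycled.
#' @param period Period, h (> 0).
#' @param times,concentrations Table of nonnegative values, `times`
#'   strictly increasing.
#' @param rule `"linear"` or `"constant"` interpolation.
#' @return An object of class `dose_schedule`.
#' @name dose_schedule
#' @seealso [evaluate_schedule()], [circadian_schedule()]
NULL

new_schedule <- function(variant, fields) {
  structure(c(list(variant = variant), fields), class = "dose_schedule")
}

check_conc <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0)) {
    stop(what, " must be nonnegative and finite")
  }
  x
}

#' @rdname dose_schedule
#' @export
schedule_constant <- function(c0) {
  new_schedule("constant", list(c0 = check_conc(c0, "c0")))
}

#' @rdname dose_schedule
#' @export
schedule_pulse <- function(c0, t_on = 0, t_off = 1) {
  check_conc(c0, "c0")
  if (!(t_off > t_on) || t_on < 0) stop("need 0 <= t_on < t_off")
  new_schedule("pulse", list(c0 = c0, t_on = t_on, t_off = t_off))
}

#' @rdname dose_schedule
#' @export
schedule_periodic <- function(mean, amplitudes = numeric(), phases = 0,
                              period = 24) {
  check_conc(mean, "mean")
  if (!is.numeric(period) || period <= 0) stop("period must be > 0")
  if (length(amplitudes)) {
    if (any(!is.finite(amplitudes))) stop("amplitudes must be finite")
    phases <- rep_len(phases, length(amplitudes))
  } else {
    phases <- numeric()
  }
  new_schedule("periodic", list(mean = mean, amplitudes = amplitudes,
                                phases = phases, period = period))
}

#' @rdname dose_schedule
#' @export
schedule_tabulated <- function(times, concentrations, rule = c("linear", "constant")) {
  rule <- match.arg(rule)
  check_conc(concentrations, "concentrations")
  if (length(times) != length(concentrations) || length(times) < 2L ||
      any(diff(times) <= 0)) {
    stop("times must be strictly increasing and match concentrations in length")
  }
  new_schedule("tabulated", list(times = times, concentrations = concentrations,
                                 rule = rule))
}

#' Evaluate a dose schedule
#'
#' @param schedule A [dose_schedule] object.
#' @param t Times in hours (vectorized, all >= 0).
#' @return Inlet concentrations at `t` (nonnegative).
#' @export
#' @examples
#' evaluate_schedule(schedule_pulse(1, 0, 1), c(0.5, 1.5))
evaluate_schedule <- function(schedule, t) {
  stopifnot(inherits(schedule, "dose_schedule"))
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0)) {
    stop("schedule evaluation requires t >= 0")
  }
  out <- switch(schedule$variant,
    constant = rep_len(schedule$c0, length(t)),
    pulse = ifelse(t >= schedule$t_on & t < schedule$t_off, schedule$c0, 0),
    periodic = {
      v <- rep_len(schedule$mean, length(t))
      amps <- schedule$amplitudes
      if (length(amps)) {
        for (k in seq_along(amps)) {
          v <- v + amps[k] *
            cos(2 * pi * k * (t - schedule$phases[k]) / schedule$period)
        }
      }
      if (any(v < 0)) {
        warning("periodic schedule evaluated negative; clipping to 0")
        v <- pmax(v, 0)
      }
      v
    },
    tabulated = {
      f <- if (schedule$rule == "linear") 1 else NULL
      stats::approx(schedule$times, schedule$concentrations, xout = t,
                    method = if (schedule$rule == "linear") "linear" else "constant",
                    rule = 2)$y
    },
    stop("unknown schedule variant"))
  out
}

#' @export
print.dose_schedule <- function(x, ...) {
  cat("<dose_schedule> variant:", x$variant, "\n")
  utils::str(unclass(x), give.attr = FALSE, no.list = TRUE)
  invisible(x)
}

#' Stand-in circadian dosing waveform
#'
#' Builds a nonnegative 24-h-periodic inlet schedule from a mean level, one
#' or more harmonic amplitudes and an acrophase (time of peak). This is a
#' parameterized stand-in for smoothed in-vivo hormone rhythms: a single
#' harmonic gives `mean + amplitude * cos(2*pi*(t - acrophase)/period)`,
#' peaking at `t = acrophase`.
#'
#' @param mean Mean concentration level (>= first amplitude, so the waveform
#'   stays nonnegative).
#' @param amplitude Amplitude of the fundamental harmonic (>= 0), or a vector
#'   of harmonic amplitudes.
#' @param acrophase Time of the fundamental's peak, h.
#' @param period Period, h (default 24).
#' @param strict If `TRUE` (default) reject parameter sets whose waveform
#'   dips negative; if `FALSE`, clip at zero (flagged by a warning on
#'   evaluation).
#' @return A periodic [dose_schedule].
#' @export
#' @examples
#' s <- circadian_schedule(mean = 1, amplitude = 0.5, acrophase = 8)
#' evaluate_schedule(s, 8)   # 1.5 at the acrophase
circadian_schedule <- function(mean, amplitude, acrophase = 0, period = 24,
                               strict = TRUE) {
  check_conc(mean, "mean")
  if (any(amplitude < 0)) stop("amplitudes must be >= 0")
  sched <- schedule_periodic(mean, amplitudes = amplitude,
                             phases = rep_len(acrophase, length(amplitude)),
                             period = period)
  tt <- seq(0, period, length.out = 481L)
  vals <- suppressWarnings(evaluate_schedule(sched, tt))
  if (strict && sum(amplitude) > mean && any(vals <= 0)) {
    stop("waveform goes negative; reduce amplitudes or set strict = FALSE")
  }
  sched
}

# Integral of the schedule over [t0, t1] by composite quadrature on the
# solver grid; exact for constant/pulse.
schedule_integral <- function(schedule, t0, t1, n = 2001L) {
  if (t1 <= t0) return(0)
  if (schedule$variant == "constant") return(schedule$c0 * (t1 - t0))
  if (schedule$variant == "pulse") {
    lo <- max(t0, schedule$t_on); hi <- min(t1, schedule$t_off)
    return(schedule$c0 * max(0, hi - lo))
  }
  tt <- seq(t0, t1, length.out = n)
  v <- suppressWarnings(evaluate_schedule(schedule, tt))
  sum((v[-1] + v[-n]) / 2) * (t1 - t0) / (n - 1)
}
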