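#' Stimulus pulse train specification
#'
#' Describes a train of symmetric, biphasic, rectangular current pulses as used
#' for epidural dorsal column stimulation: each pulse is a cathodic phase
#' immediately followed by an anodic phase of equal width and magnitude, so
#' every pulse is charge balanced by construction.
#'
#' @param frequency_hz Pulse repetition rate (pulses/s), > 0.
#' @param pulse_width_us Width of each phase (microseconds), > 0.
#' @param amplitude_ua Phase amplitude (microamperes), >= 0.
#' @param duration_s Stimulation-on duration (seconds).
#' @param onset_s Time of the first pulse (seconds, default 0).
#'
#' @return An object of class `pulse_train_spec`.
#' @export
pulse_train_spec <- function(frequency_hz, pulse_width_us, amplitude_ua,
                             duration_s, onset_s = 0) {
  stopifnot(is.numeric(frequency_hz), length(frequency_hz) == 1L,
            is.numeric(pulse_width_us), is.numeric(amplitude_ua),
            is.numeric(duration_s), is.numeric(onset_s))
  if (frequency_hz <= 0) stop("frequency_hz must be > 0")
  if (pulse_width_us <= 0) stop("pulse_width_us must be > 0")
  if (amplitude_ua < 0) stop("amplitude_ua must be >= 0")
  if (duration_s < 0) stop("duration_s must be >= 0")
  # both phases must fit within one period
  if (2 * pulse_width_us * frequency_hz > 1e6) {
    stop("biphasic pulse (2 x pulse_width) does not fit within the period")
  }
  structure(list(frequency_hz = frequency_hz,
                 pulse_width_us = pulse_width_us,
                 amplitude_ua = amplitude_ua,
                 duration_s = duration_s,
                 onset_s = onset_s,
                 shape = "symmetric-biphasic-rectangular"),
            class = "pulse_train_spec")
}

#' @export
print.pulse_train_spec <- function(x, ...) {
  cat(sprintf("pulse train: %g Hz, %g us/phase, %g uA, %g s on (onset %g s)\n",
              x$frequency_hz, x$pulse_width_us, x$amplitude_ua,
              x$duration_s, x$onset_s))
  invisible(x)
}

#' Sample a biphasic pulse train as an injected-current time series
#'
#' The cathodic phase is represented as negative current at the cathode (the
#' returned series is the current delivered through the cathodic contact; the
#' anodic contact carries the negated series). Phase edges are snapped to the
#' sampling grid; `dt_ms` must divide the phase width to within one sample.
#'
#' @param spec A [pulse_train_spec()].
#' @param dt_ms Sampling step in ms (default 0.0125, the network integration
#'   step).
#' @return A list with `time_ms`, `current_ua` (length-matched numeric
#'   vectors), `pulse_times_ms` (cathodic-phase onsets) and `dt_ms`.
#' @export
make_pulse_train <- function(spec, dt_ms = 0.0125) {
  stopifnot(inherits(spec, "pulse_train_spec"), dt_ms > 0)
  pw_ms <- spec$pulse_width_us / 1000
  n_phase <- round(pw_ms / dt_ms)
  if (n_phase < 1 || abs(n_phase * dt_ms - pw_ms) > dt_ms) {
    stop("dt_ms must divide the pulse width to within one sample")
  }
  period_ms <- 1000 / spec$frequency_hz
  if (2 * n_phase * dt_ms > period_ms) stop("phases longer than the period")
  n_pulses <- floor(spec$frequency_hz * spec$duration_s)
  total_ms <- spec$onset_s * 1000 + spec$duration_s * 1000
  n <- ceiling(total_ms / dt_ms) + 2L * n_phase + 1L  # margin for the last anodic phase
  current <- numeric(n)
  pulse_times <- spec$onset_s * 1000 + (seq_len(n_pulses) - 1L) * period_ms
  if (n_pulses > 0 && spec$amplitude_ua > 0) {
    i0 <- round(pulse_times / dt_ms)  # 0-based start sample of each pulse
    for (k in seq_len(n_pulses)) {
      a <- i0[k] + 1L
      current[a:(a + n_phase - 1L)] <- -spec$amplitude_ua
      current[(a + n_phase):(a + 2L * n_phase - 1L)] <- spec$amplitude_ua
    }
  }
  list(time_ms = (seq_len(n) - 1L) * dt_ms,
       current_ua = current,
       pulse_times_ms = pulse_times,
       dt_ms = dt_ms)
}

#' Read a stimulation configuration from YAML
#'
#' Expects a top-level `stim` mapping with keys `frequency_hz`,
#' `pulse_width_us`, `amplitude_ua`, `duration_s` and optional `onset_s`.
#'
#' @param path Path to the YAML file.
#' @return A [pulse_train_spec()].
#' @export
read_stim_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  st <- cfg$stim
  if (is.null(st)) stop("config has no 'stim' section")
  pulse_train_spec(st$frequency_hz, st$pulse_width_us, st$amplitude_ua,
                   st$duration_s, onset_s = st$onset_s %||% 0)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
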