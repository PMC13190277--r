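#' Describe a rectangular current step
#'
#' A step protocol element: a holding (baseline) current with a rectangular
#' step of given amplitude, onset and duration superimposed. Units follow the
#' pipeline convention: pA for current, seconds for protocol timing.
#'
#' @param baseline_pA Holding current in pA.
#' @param amplitude_pA Step amplitude in pA (relative to baseline; negative
#'   for hyperpolarising steps).
#' @param onset_s Step onset in seconds from the start of the sweep.
#' @param duration_s Step duration in seconds; must be positive.
#' @return An object of class `step_descriptor`.
#' @examples
#' step_descriptor(0, -100, onset_s = 0.1, duration_s = 1)
#' @export
step_descriptor <- function(baseline_pA = 0, amplitude_pA = 0,
                            onset_s = 0.1, duration_s = 1) {
  stopifnot(is.numeric(baseline_pA), is.numeric(amplitude_pA),
            is.numeric(onset_s), is.numeric(duration_s))
  if (!is.finite(duration_s) || duration_s <= 0)
    stop("step duration must be positive", call. = FALSE)
  if (!is.finite(onset_s) || onset_s < 0)
    stop("step onset must be non-negative", call. = FALSE)
  structure(
    list(baseline_pA = as.numeric(baseline_pA),
         amplitude_pA = as.numeric(amplitude_pA),
         onset_s = as.numeric(onset_s),
         duration_s = as.numeric(duration_s)),
    class = "step_descriptor")
}

#' Materialise a step descriptor as a current waveform
#'
#' @param step A [step_descriptor()].
#' @param n_samples Number of samples.
#' @param sampling_rate Sampling rate in Hz.
#' @return Numeric vector of injected current in pA, length `n_samples`.
#' @export
step_current <- function(step, n_samples, sampling_rate) {
  stopifnot(inherits(step, "step_descriptor"))
  t <- (seq_len(n_samples) - 1) / sampling_rate
  i <- rep(step$baseline_pA, n_samples)
  on <- t >= step$onset_s & t < step$onset_s + step$duration_s
  i[on] <- i[on] + step$amplitude_pA
  i
}

#' Construct a voltage sweep
#'
#' One recorded or simulated membrane-potential time series together with its
#' injected-current waveform and protocol metadata. Units are fixed
#' pipeline-wide: membrane potential in mV, current in pA, sampling rate in
#' Hz, sweep start time `t0` in seconds.
#'
#' @param voltage Numeric vector, membrane potential in mV.
#' @param current Numeric vector of injected current in pA (same length as
#'   `voltage`), or a [step_descriptor()] from which the waveform is built.
#' @param sampling_rate Sampling rate in Hz (default 50000, the native
#'   acquisition rate of the supported protocols).
#' @param sweep_id Character identifier.
#' @param t0 Start time of the sweep in seconds.
#' @param step Optional [step_descriptor()] retained as protocol metadata
#'   (set automatically when `current` is a descriptor).
#' @return An object of class `voltage_sweep` with fields `sweep_id`,
#'   `sampling_rate`, `voltage`, `current`, `step`, `t0`.
#' @export
voltage_sweep <- function(voltage, current, sampling_rate = 50000,
                          sweep_id = "sweep", t0 = 0, step = NULL) {
  if (inherits(current, "step_descriptor")) {
    step <- current
    current <- step_current(step, length(voltage), sampling_rate)
  }
  sw <- structure(
    list(sweep_id = as.character(sweep_id),
         sampling_rate = as.numeric(sampling_rate),
         voltage = as.numeric(voltage),
         current = as.numeric(current),
         step = step,
         t0 = as.numeric(t0)),
    class = "voltage_sweep")
  validate_sweep(sw)
  sw
}

validate_sweep <- function(sw) {
  if (!length(sw$voltage))
    stop("sweep has no samples", call. = FALSE)
  if (length(sw$voltage) != length(sw$current))
    stop("voltage and current must have equal length (integrity error)",
         call. = FALSE)
  if (!is.finite(sw$sampling_rate) || sw$sampling_rate <= 0)
    stop("sampling_rate must be positive", call. = FALSE)
  if (anyNA(sw$voltage) || any(!is.finite(sw$voltage)))
    stop("voltage contains non-finite samples", call. = FALSE)
  if (anyNA(sw$current) || any(!is.finite(sw$current)))
    stop("current contains non-finite samples", call. = FALSE)
  if (!is.null(sw$step)) {
    dur <- length(sw$voltage) / sw$sampling_rate
    if (sw$step$onset_s + sw$step$duration_s > dur + 1e-9)
      stop("step extends past the end of the sweep", call. = FALSE)
  }
  invisible(sw)
}

#' @export
print.voltage_sweep <- function(x, ...) {
  dur_ms <- 1000 * length(x$voltage) / x$sampling_rate
  cat(sprintf("<voltage_sweep> %s: %d samples @ %g kHz (%.1f ms)\n",
              x$sweep_id, length(x$voltage), x$sampling_rate / 1000, dur_ms))
  if (!is.null(x$step))
    cat(sprintf("  step: %+g pA at %g s for %g s (baseline %g pA)\n",
                x$step$amplitude_pA, x$step$onset_s, x$step$duration_s,
                x$step$baseline_pA))
  cat(sprintf("  V range [%.2f, %.2f] mV\n",
              min(x$voltage), max(x$voltage)))
  invisible(x)
}

#' Sample times of a sweep
#'
#' @param sweep A [voltage_sweep()].
#' @return Numeric vector of times in seconds (including `t0`).
#' @export
sweep_times <- function(sweep) {
  sweep$t0 + (seq_along(sweep$voltage) - 1) / sweep$sampling_rate
}
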