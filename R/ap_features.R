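#' @title Action-potential feature extraction
#' @description
#' Spike detection and the three AP waveform features used throughout the
#' pipeline: threshold (membrane potential at the last upward crossing of a
#' 10 V/s depolarisation-rate criterion before the peak), amplitude (peak
#' relative to threshold) and half-width (duration at 50% of amplitude above
#' threshold). All level crossings are linearly interpolated between samples;
#' dV/dt is computed by central differences at the native sampling rate.
#' @name ap-features
NULL

# central-difference dV/dt in V/s (mV/ms); endpoints use one-sided differences
dvdt <- function(v, dt_ms) {
  n <- length(v)
  d <- numeric(n)
  if (n >= 3) d[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * dt_ms)
  d[1] <- (v[2] - v[1]) / dt_ms
  d[n] <- (v[n] - v[n - 1]) / dt_ms
  d
}

#' Detect action potentials in a sweep
#'
#' Candidate peaks are local maxima preceded (within the threshold search
#' window) by an upward crossing of the dV/dt criterion; a peak must either
#' exceed the voltage floor or follow such a crossing. Peaks closer than the
#' refractory guard are merged, keeping the higher one. Returns an empty
#' collection (not an error) when the sweep contains no spikes.
#'
#' @param sweep A [voltage_sweep()].
#' @param dvdt_threshold dV/dt criterion, V/s (default 10).
#' @param peak_floor_mV Voltage floor for peak candidacy, mV (default 0).
#' @param min_separation_ms Refractory guard between peaks, ms (default 1).
#' @param search_window_ms Window after a dV/dt crossing within which the
#'   peak is sought, ms (default 5).
#' @return A list of `spike_event` objects (fields `peak_index`, `peak_mV`,
#'   `threshold_index`, `threshold_mV`), ordered in time.
#' @export
detect_spikes <- function(sweep, dvdt_threshold = 10, peak_floor_mV = 0,
                          min_separation_ms = 1, search_window_ms = 5) {
  validate_sweep(sweep)
  v <- sweep$voltage
  n <- length(v)
  if (n < 3) return(list())
  dt_ms <- 1000 / sweep$sampling_rate
  d <- dvdt(v, dt_ms)
  up <- which(d[-n] < dvdt_threshold & d[-1] >= dvdt_threshold)
  if (!length(up)) return(list())
  win <- max(1L, round(search_window_ms / dt_ms))
  peaks <- integer(0)
  for (u in up) {
    hi <- min(n, u + win)
    seg <- v[(u + 1):hi]
    p <- u + which.max(seg)
    # local maximum: next sample (if any) does not exceed it
    if (p < n && v[p + 1] > v[p]) next
    if (v[p] < peak_floor_mV && d[u + 1] < dvdt_threshold) next
    peaks <- c(peaks, p)
  }
  if (!length(peaks)) return(list())
  peaks <- sort(unique(peaks))
  guard <- max(1L, round(min_separation_ms / dt_ms))
  keep <- integer(0)
  for (p in peaks) {
    if (length(keep) && p - keep[length(keep)] < guard) {
      if (v[p] > v[keep[length(keep)]]) keep[length(keep)] <- p
    } else keep <- c(keep, p)
  }
  lapply(keep, function(p) {
    thr <- threshold_crossing(v, d, p, dvdt_threshold, win, dt_ms)
    structure(list(peak_index = p, peak_mV = v[p],
                   threshold_index = if (is.null(thr)) NA_integer_
                                     else thr$index,
                   threshold_mV = if (is.null(thr)) NA_real_ else thr$mV),
              class = "spike_event")
  })
}

# last upward crossing of the dV/dt criterion before peak p, interpolated
threshold_crossing <- function(v, d, p, crit, win, dt_ms) {
  lo <- max(1L, p - win)
  if (p - lo < 1L) return(NULL)
  idx <- lo:(p - 1L)
  cross <- idx[d[idx] < crit & d[idx + 1L] >= crit]
  if (!length(cross)) {
    # boundary case: criterion already met at the window start (e.g. a ramp
    # of exactly the criterion slope) -> first sample of the window
    if (all(d[lo:p] >= crit)) return(list(index = lo, mV = v[lo]))
    return(NULL)
  }
  i <- cross[length(cross)]          # ties -> latest crossing
  f <- (crit - d[i]) / (d[i + 1L] - d[i])
  list(index = i, mV = v[i] + f * (v[i + 1L] - v[i]))
}

#' AP threshold of a detected spike
#'
#' Membrane potential at the last upward crossing of the dV/dt criterion
#' (default 10 V/s) before the spike peak, searched backward within a 5-ms
#' window, with linear interpolation between samples.
#'
#' @param sweep A [voltage_sweep()].
#' @param spike A `spike_event` from [detect_spikes()].
#' @param dvdt_threshold dV/dt criterion, V/s.
#' @param search_window_ms Backward search window, ms.
#' @return Threshold in mV, or `NA` with attribute `undefined = TRUE` when
#'   no crossing exists in the window.
#' @export
ap_threshold <- function(sweep, spike, dvdt_threshold = 10,
                         search_window_ms = 5) {
  stopifnot(inherits(spike, "spike_event"))
  v <- sweep$voltage
  dt_ms <- 1000 / sweep$sampling_rate
  d <- dvdt(v, dt_ms)
  win <- max(1L, round(search_window_ms / dt_ms))
  thr <- threshold_crossing(v, d, spike$peak_index, dvdt_threshold, win, dt_ms)
  if (is.null(thr))
    return(structure(NA_real_, undefined = TRUE))
  thr$mV
}

#' AP amplitude of a detected spike
#'
#' Peak potential minus threshold potential. A non-positive amplitude is
#' returned as `NA` with `undefined = TRUE` (degenerate event).
#'
#' @inheritParams ap_threshold
#' @return Amplitude in mV.
#' @export
ap_amplitude <- function(sweep, spike, dvdt_threshold = 10,
                         search_window_ms = 5) {
  thr <- ap_threshold(sweep, spike, dvdt_threshold, search_window_ms)
  if (is.na(thr)) return(structure(NA_real_, undefined = TRUE))
  amp <- spike$peak_mV - thr
  if (amp <= 0) return(structure(NA_real_, undefined = TRUE))
  amp
}

# interpolated time (in samples, fractional) where v crosses `level`
# upward (dir = 1) or downward (dir = -1), searching idx range
interp_crossing <- function(v, level, from, to, dir) {
  idx <- from:(to - 1L)
  hit <- if (dir > 0) idx[v[idx] < level & v[idx + 1L] >= level]
         else idx[v[idx] >= level & v[idx + 1L] < level]
  if (!length(hit)) return(NA_real_)
  i <- hit[1]
  i + (level - v[i]) / (v[i + 1L] - v[i])
}

#' AP half-width of a detected spike
#'
#' Time between the interpolated upward and downward crossings of
#' `threshold + amplitude/2`. Returns `NA` (flagged) when the downstroke is
#' truncated by the sweep end.
#'
#' @inheritParams ap_threshold
#' @param max_width_ms Downstroke search limit after the peak, ms.
#' @return Half-width in ms.
#' @export
ap_half_width <- function(sweep, spike, dvdt_threshold = 10,
                          search_window_ms = 5, max_width_ms = 10) {
  thr <- ap_threshold(sweep, spike, dvdt_threshold, search_window_ms)
  if (is.na(thr)) return(structure(NA_real_, undefined = TRUE))
  amp <- spike$peak_mV - thr
  if (amp <= 0) return(structure(NA_real_, undefined = TRUE))
  level <- thr + amp / 2
  v <- sweep$voltage
  dt_ms <- 1000 / sweep$sampling_rate
  p <- spike$peak_index
  lo <- max(1L, p - round(search_window_ms / dt_ms))
  hi <- min(length(v), p + round(max_width_ms / dt_ms))
  t_up <- interp_crossing(v, level, lo, p, dir = 1)
  t_dn <- interp_crossing(v, level, p, hi, dir = -1)
  if (is.na(t_up) || is.na(t_dn))
    return(structure(NA_real_, undefined = TRUE))
  (t_dn - t_up) * dt_ms
}

#' Extract the full AP feature set from one sweep
#'
#' Convenience wrapper: detects spikes and measures threshold, amplitude and
#' half-width of the `which` spike (default first).
#'
#' @param sweep A [voltage_sweep()].
#' @param which Index of the spike to measure.
#' @param ... Passed to [detect_spikes()].
#' @return An `ap_feature_set` (fields `threshold_mV`, `amplitude_mV`,
#'   `half_width_ms`, `n_traces_averaged = 1`), or `NULL` when the sweep has
#'   no spikes.
#' @export
ap_features <- function(sweep, which = 1, ...) {
  ev <- detect_spikes(sweep, ...)
  if (length(ev) < which) return(NULL)
  sp <- ev[[which]]
  structure(list(threshold_mV = as.numeric(ap_threshold(sweep, sp)),
                 amplitude_mV = as.numeric(ap_amplitude(sweep, sp)),
                 half_width_ms = as.numeric(ap_half_width(sweep, sp)),
                 n_traces_averaged = 1L),
            class = "ap_feature_set")
}

#' Average AP features across repeat traces
#'
#' Arithmetic mean per feature over (normally two) repeat single-AP traces.
#' A single defined input is returned as-is with a warning and a flag, per
#' the two-trace averaging convention.
#'
#' @param a,b `ap_feature_set` objects (either may be `NULL`/undefined).
#' @return An `ap_feature_set` with `n_traces_averaged` recording how many
#'   traces contributed; attribute `partial = TRUE` when only one did.
#' @export
average_ap_features <- function(a, b) {
  ok <- function(x) !is.null(x) && !any(is.na(unlist(x[1:3])))
  if (!ok(a) && !ok(b)) stop("no defined feature set to average", call. = FALSE)
  if (!ok(a) || !ok(b)) {
    keep <- if (ok(a)) a else b
    warning("averaging a single AP trace (repeat missing or undefined)")
    keep$n_traces_averaged <- 1L
    attr(keep, "partial") <- TRUE
    return(keep)
  }
  structure(list(threshold_mV = (a$threshold_mV + b$threshold_mV) / 2,
                 amplitude_mV = (a$amplitude_mV + b$amplitude_mV) / 2,
                 half_width_ms = (a$half_width_ms + b$half_width_ms) / 2,
                 n_traces_averaged = 2L),
            class = "ap_feature_set")
}

#' @export
print.ap_feature_set <- function(x, ...) {
  cat(sprintf(
    "<ap_feature_set> threshold %.2f mV, amplitude %.2f mV, half-width %.3f ms (n=%d)\n",
    x$threshold_mV, x$amplitude_mV, x$half_width_ms, x$n_traces_averaged))
  invisible(x)
}
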