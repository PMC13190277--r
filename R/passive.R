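#' @title Passive membrane properties and protocol QC
#' @description
#' Resting membrane potential, input resistance (regression of steady-state
#' voltage deflection on injected current), membrane time constant
#' (exponential fit `V(t) = y0 + A exp(-(t - X0)/tau)` to the charging
#' phase), capacitance (`tau / R_in`), rheobase from the two-repeat step
#' protocol, and the series-resistance exclusion rule.
#' @name passive-properties
NULL

#' Resting membrane potential
#'
#' Mean of the pre-stimulus baseline window (default the 100 ms immediately
#' preceding the step onset; for sweeps without a step descriptor, the first
#' `window_ms` of the sweep).
#'
#' @param sweep A [voltage_sweep()].
#' @param window_ms Baseline window length, ms.
#' @return RMP in mV.
#' @export
resting_membrane_potential <- function(sweep, window_ms = 100) {
  validate_sweep(sweep)
  rate <- sweep$sampling_rate
  n_win <- round(window_ms / 1000 * rate)
  if (n_win < 1) stop("baseline window too short", call. = FALSE)
  end <- if (!is.null(sweep$step)) round(sweep$step$onset_s * rate)
         else n_win
  if (end < n_win)
    stop("baseline window longer than the pre-stimulus period", call. = FALSE)
  mean(sweep$voltage[(end - n_win + 1):end])
}

steady_state_dv <- function(sweep, rmp, window_ms = 100) {
  st <- sweep$step
  if (is.null(st)) stop("sweep lacks a step descriptor", call. = FALSE)
  rate <- sweep$sampling_rate
  i_off <- round((st$onset_s + st$duration_s) * rate)
  n_win <- round(window_ms / 1000 * rate)
  mean(sweep$voltage[(i_off - n_win + 1):i_off]) - rmp
}

#' Input resistance from a hyperpolarising step family
#'
#' Steady-state voltage deflection (mean of the final `window_ms` of each
#' step) relative to the RMP is regressed on injected current by ordinary
#' least squares; the slope, converted to MΩ, is the input resistance.
#'
#' @param sweeps List of [voltage_sweep()] objects with step descriptors
#'   (at least two distinct amplitudes, e.g. -25..-100 pA).
#' @param rmp Resting membrane potential, mV (default: measured from the
#'   first sweep).
#' @param window_ms Steady-state window, ms.
#' @return Input resistance in MΩ with attributes `fit` (the `lm` object)
#'   and `data` (deflection vs current table).
#' @export
input_resistance <- function(sweeps, rmp = NULL, window_ms = 100) {
  if (inherits(sweeps, "voltage_sweep")) sweeps <- list(sweeps)
  amps <- vapply(sweeps, function(s) s$step$amplitude_pA, 0)
  if (length(unique(amps)) < 2)
    stop("insufficient data: need >= 2 distinct step amplitudes",
         call. = FALSE)
  if (is.null(rmp)) rmp <- resting_membrane_potential(sweeps[[1]])
  dv <- vapply(sweeps, steady_state_dv, 0, rmp = rmp, window_ms = window_ms)
  fit <- stats::lm(dv ~ amps)
  r_mohm <- unname(stats::coef(fit)[2]) * 1000   # mV/pA -> MOhm
  structure(r_mohm, fit = fit,
            data = data.frame(amplitude_pA = amps, dv_mV = dv))
}

#' Membrane time constant from one hyperpolarising step
#'
#' Nonlinear least-squares fit of `V(t) = y0 + A exp(-(t - X0)/tau)` to the
#' charging phase. `X0` is fixed at the step onset; the first
#' `skip_samples` after onset are excluded (pipette transient) and the
#' window spans `n_tau` estimated time constants (the estimate from the 63%
#' crossing, iterated once after fitting). Initialisation is deterministic:
#' `y0` = steady-state mean, `A` = onset-minus-steady difference, `tau` =
#' time to 63% of the deflection.
#'
#' @param sweep A [voltage_sweep()] with a hyperpolarising step descriptor.
#' @param skip_samples Samples skipped after onset.
#' @param n_tau Fit window length in estimated time constants.
#' @param window_ms Steady-state window used for initialisation, ms.
#' @return An `exponential_fit` object: `y0`, `A`, `X0` (ms), `tau` (ms),
#'   `rss` (mV²), `converged`. On non-convergence `converged` is `FALSE`
#'   and `tau` is `NA`.
#' @export
membrane_time_constant <- function(sweep, skip_samples = 2, n_tau = 5,
                                   window_ms = 100) {
  validate_sweep(sweep)
  st <- sweep$step
  if (is.null(st)) stop("sweep lacks a step descriptor", call. = FALSE)
  rate <- sweep$sampling_rate
  dt_ms <- 1000 / rate
  i_on <- round(st$onset_s * rate) + 1L
  i_off <- round((st$onset_s + st$duration_s) * rate)
  v <- sweep$voltage
  rmp <- resting_membrane_potential(sweep)
  n_ss <- round(window_ms / 1000 * rate)
  y0_init <- mean(v[(i_off - n_ss + 1):i_off])
  A_init <- rmp - y0_init
  fail <- function() structure(
    list(y0 = y0_init, A = A_init, X0 = (i_on - 1) * dt_ms, tau = NA_real_,
         rss = NA_real_, converged = FALSE),
    class = "exponential_fit")
  if (abs(A_init) < 1e-8) return(fail())   # flat trace: degenerate
  # initial tau: time to reach 63.2% of the deflection
  target <- rmp - 0.632 * A_init
  rel <- if (A_init > 0) which(v[i_on:i_off] <= target)
         else which(v[i_on:i_off] >= target)
  if (!length(rel)) return(fail())
  tau_init <- max(rel[1] * dt_ms, dt_ms)

  fit_once <- function(tau_est) {
    i_end <- min(i_off, i_on + round(n_tau * tau_est / dt_ms))
    idx <- (i_on + skip_samples):i_end
    if (length(idx) < 5) return(NULL)
    tt <- (idx - i_on) * dt_ms       # ms from onset (X0 fixed at onset)
    df <- data.frame(tt = tt, vv = v[idx])
    tryCatch(
      minpack.lm::nlsLM(vv ~ y0 + A * exp(-tt / tau), data = df,
                        start = list(y0 = y0_init, A = A_init,
                                     tau = tau_est),
                        control = minpack.lm::nls.lm.control(maxiter = 100)),
      error = function(e) NULL)
  }
  fit <- fit_once(tau_init)
  if (!is.null(fit)) {
    tau1 <- stats::coef(fit)[["tau"]]
    if (is.finite(tau1) && tau1 > 0) {
      refit <- fit_once(tau1)        # re-window at 5 fitted taus, once
      if (!is.null(refit)) fit <- refit
    }
  }
  if (is.null(fit)) return(fail())
  cf <- stats::coef(fit)
  if (!is.finite(cf[["tau"]]) || cf[["tau"]] <= 0) return(fail())
  structure(list(y0 = unname(cf[["y0"]]), A = unname(cf[["A"]]),
                 X0 = (i_on - 1) * dt_ms, tau = unname(cf[["tau"]]),
                 rss = sum(stats::resid(fit)^2), converged = TRUE),
            class = "exponential_fit")
}

#' @export
print.exponential_fit <- function(x, ...) {
  if (x$converged)
    cat(sprintf("<exponential_fit> tau %.3f ms (y0 %.2f, A %.2f, rss %.3g)\n",
                x$tau, x$y0, x$A, x$rss))
  else cat("<exponential_fit> not converged\n")
  invisible(x)
}

#' Membrane capacitance from time constant and input resistance
#'
#' `C = tau / R_in`, with the pipeline unit convention
#' `pF = 1000 * tau[ms] / R[MΩ]` (dimension-exact).
#'
#' @param tau_ms Membrane time constant, ms.
#' @param r_in_mohm Input resistance, MΩ (> 0).
#' @return Capacitance in pF.
#' @examples
#' membrane_capacitance(20, 200)    # 100 pF
#' @export
membrane_capacitance <- function(tau_ms, r_in_mohm) {
  if (!is.finite(r_in_mohm) || r_in_mohm <= 0)
    stop("input resistance must be positive", call. = FALSE)
  1000 * tau_ms / r_in_mohm
}

#' Rheobase from the two-repeat step protocol
#'
#' Per repeat, the lowest step amplitude with at least one detected spike;
#' the reported rheobase is the mean over the two repeats. A repeat without
#' any spiking step yields `NA` for that repeat (flagged).
#'
#' @param repeat1,repeat2 Sweep families (lists of [voltage_sweep()]) from
#'   the two I-F protocol runs. `repeat2` may be `NULL`.
#' @param ... Passed to [detect_spikes()].
#' @return Rheobase in pA (`NA` if undefined in all repeats), with attribute
#'   `per_repeat` holding the per-repeat minima.
#' @export
rheobase <- function(repeat1, repeat2 = NULL, ...) {
  one <- function(sweeps) {
    if (is.null(sweeps)) return(NA_real_)
    amps <- vapply(sweeps, function(s) s$step$amplitude_pA, 0)
    spk <- vapply(sweeps, function(s) length(detect_spikes(s, ...)) > 0, TRUE)
    if (!any(spk)) return(NA_real_)
    min(amps[spk])
  }
  per <- c(one(repeat1), one(repeat2))
  if (is.null(repeat2)) per <- per[1]
  val <- if (all(is.na(per))) NA_real_ else mean(per, na.rm = TRUE)
  structure(val, per_repeat = per)
}

#' Series-resistance quality-control rule
#'
#' A recording fails QC when the series resistance changes by more than 20%
#' between the pre- and post-protocol checks (boundary values pass).
#'
#' @param rs_before_mohm,rs_after_mohm Series resistance, MΩ.
#' @param max_change Maximal tolerated fractional change (default 0.20).
#' @return List with `pass` (logical) and `pct_change` (signed percent).
#' @export
series_resistance_qc <- function(rs_before_mohm, rs_after_mohm,
                                 max_change = 0.20) {
  if (rs_before_mohm <= 0) stop("series resistance must be positive",
                                call. = FALSE)
  frac <- (rs_after_mohm - rs_before_mohm) / rs_before_mohm
  list(pass = abs(frac) <= max_change, pct_change = 100 * frac)
}

#' Full passive characterisation of one cell
#'
#' Convenience wrapper combining RMP, input resistance, time constant
#' (fitted per hyperpolarising step; converged fits averaged), capacitance
#' and rheobase into a `passive_result`.
#'
#' @param hyper_sweeps Hyperpolarising step family.
#' @param if_repeat1,if_repeat2 I-F protocol repeats (for rheobase); may be
#'   `NULL`.
#' @param rs_before_mohm,rs_after_mohm Optional series-resistance checks.
#' @return A `passive_result` list: `rmp_mV`, `r_in_mohm`, `tau_ms`,
#'   `capacitance_pF`, `rheobase_pA`, `series_r_change_pct`, `qc_pass`.
#' @export
passive_result <- function(hyper_sweeps, if_repeat1 = NULL, if_repeat2 = NULL,
                           rs_before_mohm = NA, rs_after_mohm = NA) {
  rmp <- resting_membrane_potential(hyper_sweeps[[1]])
  r_in <- as.numeric(input_resistance(hyper_sweeps, rmp = rmp))
  fits <- lapply(hyper_sweeps, membrane_time_constant)
  taus <- vapply(fits, function(f) if (f$converged) f$tau else NA_real_, 0)
  tau <- mean(taus, na.rm = TRUE)
  qc <- if (is.finite(rs_before_mohm) && is.finite(rs_after_mohm))
    series_resistance_qc(rs_before_mohm, rs_after_mohm)
  else list(pass = NA, pct_change = NA_real_)
  rb <- if (!is.null(if_repeat1)) as.numeric(rheobase(if_repeat1, if_repeat2))
        else NA_real_
  structure(list(rmp_mV = rmp, r_in_mohm = r_in, tau_ms = tau,
                 capacitance_pF = membrane_capacitance(tau, r_in),
                 rheobase_pA = rb,
                 series_r_change_pct = qc$pct_change, qc_pass = qc$pass),
            class = "passive_result")
}
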