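make_spike_event <- function(peak_index, peak_mV,
                             threshold_index = NA_integer_,
                             threshold_mV = NA_real_) {
  structure(list(peak_index = peak_index, peak_mV = peak_mV,
                 threshold_index = threshold_index,
                 threshold_mV = threshold_mV), class = "spike_event")
}

test_that("detected spike count equals the simulator's ground truth", {
  m <- default_spiking()
  fam <- simulate_spiking(m, step_grid(from = 0, to = 500))
  truth <- attr(fam, "truth")
  for (k in seq_along(fam))
    expect_length(detect_spikes(fam[[k]]), truth$n_spikes[k])
})

test_that("passive sweeps yield zero spike events", {
  sw <- hyper_family()[[1]]
  expect_length(detect_spikes(sw), 0)
})

test_that("two APs three milliseconds apart are resolved with the 1 ms guard", {
  # paint two templates by hand on a quiet baseline
  m <- default_spiking()
  rate <- 50000
  v <- rep(-70, 0.05 * rate)
  tpl <- aisephys:::ap_template(m, 1000 / rate)
  for (at in c(1000, 1000 + 0.003 * rate))
    v[at:(at + length(tpl$values) - 1)] <- tpl$values
  sw <- voltage_sweep(v, rep(0, length(v)), sampling_rate = rate)
  ev <- detect_spikes(sw)
  expect_length(ev, 2)
  # brute-force check of the peak positions
  expect_equal(vapply(ev, `[[`, 0L, "peak_index") |> sort(),
               which(v == max(v)) |> sort())
})

test_that("AP threshold recovers the template threshold within half a millivolt", {
  m <- default_spiking()
  fam <- simulate_spiking(m, step_descriptor(0, 375, 0.1, 1))
  sw <- fam[[1]]
  ev <- detect_spikes(sw)
  expect_gt(length(ev), 0)
  for (sp in ev)
    expect_lt(abs(ap_threshold(sw, sp) - m$V_T), 0.5)
})

test_that("a ramp of exactly the criterion slope thresholds at the window start", {
  rate <- 50000
  dt_ms <- 1000 / rate
  n <- 500
  # 0.25 mV/sample = 12.5 V/s: increment and slope exactly representable,
  # so dV/dt equals the criterion at every sample
  v <- -70 + 0.25 * (seq_len(n) - 1)
  sw <- voltage_sweep(v, rep(0, n), sampling_rate = rate)
  sp <- make_spike_event(n, v[n])
  win <- round(5 / dt_ms)
  expect_equal(as.numeric(ap_threshold(sw, sp, dvdt_threshold = 12.5)),
               v[n - win])
})

test_that("threshold is flagged undefined when no crossing exists", {
  sw <- hyper_family()[[1]]
  sp <- make_spike_event(1000, sw$voltage[1000])
  th <- ap_threshold(sw, sp)
  expect_true(is.na(th))
  expect_true(attr(th, "undefined"))
})

test_that("amplitude is the peak relative to threshold", {
  m <- default_spiking()
  sw <- simulate_spiking(m, step_descriptor(0, 375, 0.1, 1))[[1]]
  ev <- detect_spikes(sw)
  amp <- ap_amplitude(sw, ev[[1]])
  expect_lt(abs(amp - 100), 1)
  # brute force: max minus measured threshold over the spike neighbourhood
  thr <- ap_threshold(sw, ev[[1]])
  expect_equal(as.numeric(amp), ev[[1]]$peak_mV - as.numeric(thr))
})

test_that("half-width equals (rise + fall)/2 for the triangular template", {
  m <- default_spiking()   # rise 0.2, fall 0.6 -> 0.4 ms
  sw <- simulate_spiking(m, step_descriptor(0, 375, 0.1, 1))[[1]]
  ev <- detect_spikes(sw)
  expect_equal(as.numeric(ap_half_width(sw, ev[[1]])), 0.4, tolerance = 0.02)
  # symmetric template: rise = fall = 0.5 -> 0.5 ms
  ms <- spiking_model(ap_rise_ms = 0.5, ap_fall_ms = 0.5, t_ref = 2,
                      ap_peak_amp = 100)
  sw2 <- simulate_spiking(ms, step_descriptor(0, 375, 0.1, 1))[[1]]
  ev2 <- detect_spikes(sw2)
  expect_equal(as.numeric(ap_half_width(sw2, ev2[[1]])), 0.5,
               tolerance = 0.02)
})

test_that("half-width agrees with a dense brute-force crossing search", {
  m <- default_spiking()
  sw <- simulate_spiking(m, step_descriptor(0, 300, 0.05, 0.5))[[1]]
  ev <- detect_spikes(sw)
  sp <- ev[[1]]
  hw <- as.numeric(ap_half_width(sw, sp))
  # oracle: 10x oversampled linear interpolation of the trace, direct scan
  thr <- as.numeric(ap_threshold(sw, sp))
  level <- thr + (sp$peak_mV - thr) / 2
  idx <- max(1, sp$peak_index - 250):min(length(sw$voltage),
                                         sp$peak_index + 500)
  t_ms <- (idx - 1) / sw$sampling_rate * 1000
  fine_t <- seq(min(t_ms), max(t_ms), length.out = length(idx) * 10)
  fine_v <- approx(t_ms, sw$voltage[idx], xout = fine_t)$y
  above <- fine_v >= level
  oracle <- fine_t[max(which(above))] - fine_t[min(which(above))]
  expect_lt(abs(hw - oracle), 1000 / sw$sampling_rate)  # within one sample
})

test_that("half-width is flagged when the downstroke is truncated", {
  m <- default_spiking()
  rate <- 50000
  tpl <- aisephys:::ap_template(m, 1000 / rate)
  n_rise <- round(m$ap_rise_ms * rate / 1000)
  v <- c(rep(-70, 500), tpl$values[seq_len(n_rise + 2)])  # cut mid-fall
  sw <- voltage_sweep(v, rep(0, length(v)), sampling_rate = rate)
  ev <- detect_spikes(sw)
  expect_length(ev, 1)
  hw <- ap_half_width(sw, ev[[1]])
  expect_true(is.na(hw))
  expect_true(attr(hw, "undefined"))
})

test_that("feature averaging follows the two-trace convention", {
  f1 <- structure(list(threshold_mV = -44, amplitude_mV = 99,
                       half_width_ms = 0.39, n_traces_averaged = 1L),
                  class = "ap_feature_set")
  f2 <- structure(list(threshold_mV = -46, amplitude_mV = 101,
                       half_width_ms = 0.41, n_traces_averaged = 1L),
                  class = "ap_feature_set")
  avg <- average_ap_features(f1, f2)
  expect_equal(avg$threshold_mV, -45)
  expect_equal(avg$amplitude_mV, 100)
  expect_equal(avg$half_width_ms, 0.40)
  expect_equal(avg$n_traces_averaged, 2L)
  same <- average_ap_features(f1, f1)
  expect_equal(same$threshold_mV, f1$threshold_mV)
  # one undefined input: other returned with a warning and a flag
  bad <- structure(list(threshold_mV = NA_real_, amplitude_mV = NA_real_,
                        half_width_ms = NA_real_, n_traces_averaged = 1L),
                   class = "ap_feature_set")
  expect_warning(part <- average_ap_features(f1, bad), "single")
  expect_equal(part$threshold_mV, f1$threshold_mV)
  expect_true(attr(part, "partial"))
  expect_error(suppressWarnings(average_ap_features(bad, bad)), "no defined")
})

test_that("features recover ground truth across a random parameter sweep", {
  set.seed(77)
  rate <- 50000
  dt_ms <- 1000 / rate
  for (k in 1:50) {
    # template durations drawn on the sampling grid; slope kept >= 50 V/s
    rise <- sample(5:25, 1) * dt_ms
    fall <- sample(10:50, 1) * dt_ms
    amp <- runif(1, max(60, 55 * rise), 120)
    vt <- runif(1, -50, -40)
    m <- spiking_model(E_L = -70, R_in = runif(1, 80, 200),
                       tau_m = runif(1, 10, 30),
                       V_T = vt, V_reset = vt - runif(1, 5, 20),
                       t_ref = rise + fall + runif(1, 0.5, 2),
                       ap_peak_amp = amp, ap_rise_ms = rise,
                       ap_fall_ms = fall)
    i_step <- (m$V_T - m$E_L) / m$R_in * 1000 + 150
    sw <- simulate_spiking(m, step_descriptor(0, i_step, 0.05, 0.4))[[1]]
    ev <- detect_spikes(sw)
    expect_gt(length(ev), 0)
    sp <- ev[[1]]
    expect_lt(abs(as.numeric(ap_threshold(sw, sp)) - m$V_T), 0.5)
    expect_lt(abs(as.numeric(ap_amplitude(sw, sp)) - m$ap_peak_amp), 1)
    tpl <- aisephys:::ap_template(m, dt_ms)
    expect_lt(abs(as.numeric(ap_half_width(sw, sp)) - tpl$half_width_ms),
              2 * dt_ms)
  }
})

test_that("amplitude and half-width are invariant to a constant voltage offset", {
  m <- default_spiking()
  sw <- simulate_spiking(m, step_descriptor(0, 375, 0.1, 0.5))[[1]]
  ev <- detect_spikes(sw)
  sp <- ev[[1]]
  off <- 7.3
  sw2 <- voltage_sweep(sw$voltage + off, sw$current,
                       sampling_rate = sw$sampling_rate, step = sw$step)
  ev2 <- detect_spikes(sw2)
  sp2 <- ev2[[1]]
  expect_equal(sp2$peak_index, sp$peak_index)
  expect_equal(as.numeric(ap_threshold(sw2, sp2)),
               as.numeric(ap_threshold(sw, sp)) + off, tolerance = 1e-9)
  expect_equal(as.numeric(ap_amplitude(sw2, sp2)),
               as.numeric(ap_amplitude(sw, sp)), tolerance = 1e-9)
  expect_equal(as.numeric(ap_half_width(sw2, sp2)),
               as.numeric(ap_half_width(sw, sp)), tolerance = 1e-9)
})
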