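# Shared fixtures: canonical models and protocols used across test files.

default_passive <- function(noise_sd = 0)
  passive_model(E_L = -70, R_in = 150, tau_m = 20, noise_sd = noise_sd)

# LIF with grid rheobase (V_T - E_L)/R = 25 mV -> 250 pA on the 25 pA grid
default_spiking <- function(noise_sd = 0)
  spiking_model(E_L = -70, R_in = 100, tau_m = 20, noise_sd = noise_sd,
                V_T = -45, V_reset = -60, t_ref = 2,
                ap_peak_amp = 100, ap_rise_ms = 0.2, ap_fall_ms = 0.6)

hyper_family <- function(model = default_passive(), rate = 50000) {
  simulate_passive(model,
                   lapply(c(-25, -50, -75, -100),
                          function(a) step_descriptor(0, a, 0.1, 1)),
                   rate = rate)
}

# closed-form LIF oracle: spike count over a 1-s step (independent of the
# simulator's integration path)
lif_count_oracle <- function(model, i_pA, duration_ms = 1000) {
  dv <- i_pA * model$R_in / 1000
  v_inf <- model$E_L + dv
  if (v_inf < model$V_T) return(0L)
  t_first <- if (v_inf == model$V_T) {
    model$tau_m * log((v_inf - model$E_L) / 1e-6)   # time to numerical contact
  } else {
    model$tau_m * log((v_inf - model$E_L) / (v_inf - model$V_T))
  }
  if (t_first > duration_ms) return(0L)
  isi <- if (v_inf == model$V_T) {
    model$t_ref + model$tau_m * log((v_inf - model$V_reset) / 1e-6)
  } else {
    model$t_ref + model$tau_m * log((v_inf - model$V_reset) /
                                      (v_inf - model$V_T))
  }
  as.integer(1 + floor((duration_ms - t_first) / isi))
}

# steady-state LIF firing rate (Hz), standard ISI formula
lif_rate_oracle <- function(model, i_pA) {
  dv <- i_pA * model$R_in / 1000
  v_inf <- model$E_L + dv
  if (v_inf <= model$V_T) return(0)
  1000 / (model$t_ref + model$tau_m *
            log((v_inf - model$V_reset) / (v_inf - model$V_T)))
}
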