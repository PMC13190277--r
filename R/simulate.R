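#' @title Synthetic-data generators
#' @description
#' Generators for passive (RC) and spiking current-clamp sweeps, trapezoidal
#' AIS fluorescence profiles, serial lesion sections, and hierarchical
#' factorial cohorts. Each generator emits a machine-readable ground-truth
#' record (attribute `"truth"`) so every analysis stage has a
#' parameter-recovery test. Identical seeds give identical outputs.
#' @name synthetic-data
NULL

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' Passive membrane model
#'
#' A single-compartment RC description of the subthreshold membrane:
#' resting potential `E_L` (mV), input resistance `R_in` (MΩ), membrane time
#' constant `tau_m` (ms), plus i.i.d. Gaussian recording noise `noise_sd`
#' (mV) added to the emitted samples.
#'
#' @param E_L Resting potential, mV.
#' @param R_in Input resistance, MΩ (> 0).
#' @param tau_m Membrane time constant, ms (> 0).
#' @param noise_sd Recording-noise SD, mV (>= 0).
#' @return An object of class `passive_model`.
#' @export
passive_model <- function(E_L = -70, R_in = 150, tau_m = 20, noise_sd = 0) {
  if (R_in <= 0) stop("R_in must be positive", call. = FALSE)
  if (tau_m <= 0) stop("tau_m must be positive", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  structure(list(E_L = E_L, R_in = R_in, tau_m = tau_m, noise_sd = noise_sd),
            class = "passive_model")
}

#' Spiking (leaky integrate-and-fire) model
#'
#' Extends [passive_model()] with a spike threshold `V_T`, reset `V_reset`,
#' refractory period `t_ref`, and a piecewise-linear AP template: a linear
#' rise of `ap_rise_ms` from `V_T` to `V_T + ap_peak_amp`, a linear fall of
#' `ap_fall_ms` back to `V_T`, then a linear descent to `V_reset` over the
#' remainder of the refractory period. The template therefore has closed-form
#' features: amplitude `ap_peak_amp` above threshold and half-width
#' `(ap_rise_ms + ap_fall_ms)/2`. Template durations are quantised to the
#' sampling grid at simulation time (effective values are reported in the
#' ground-truth record) so these oracles hold exactly on the sampled trace.
#'
#' @inheritParams passive_model
#' @param V_T Spike threshold, mV (> `E_L`).
#' @param V_reset Post-spike reset potential, mV (<= `V_T`).
#' @param t_ref Refractory period, ms (>= `ap_rise_ms + ap_fall_ms`).
#' @param ap_peak_amp Template peak above `V_T`, mV.
#' @param ap_rise_ms Rise time from threshold to peak, ms.
#' @param ap_fall_ms Fall time from peak back to threshold, ms.
#' @return An object of class `spiking_model` (inherits `passive_model`).
#' @export
spiking_model <- function(E_L = -70, R_in = 100, tau_m = 20, noise_sd = 0,
                          V_T = -45, V_reset = -60, t_ref = 2,
                          ap_peak_amp = 100, ap_rise_ms = 0.2,
                          ap_fall_ms = 0.6) {
  base <- passive_model(E_L, R_in, tau_m, noise_sd)
  if (V_T <= E_L) stop("V_T must exceed E_L", call. = FALSE)
  if (V_reset > V_T) stop("V_reset must not exceed V_T", call. = FALSE)
  if (t_ref < ap_rise_ms + ap_fall_ms)
    stop("refractory period shorter than the AP template", call. = FALSE)
  if (ap_peak_amp / ap_rise_ms < 50)
    stop("template initial slope must be >= 50 V/s", call. = FALSE)
  structure(c(base, list(V_T = V_T, V_reset = V_reset, t_ref = t_ref,
                         ap_peak_amp = ap_peak_amp, ap_rise_ms = ap_rise_ms,
                         ap_fall_ms = ap_fall_ms)),
            class = c("spiking_model", "passive_model"))
}

# exact discrete subthreshold LIF update (exponential Euler): for
# piecewise-constant drive D, V[n] = D[n] + (V[n-1] - D[n]) * exp(-dt/tau)
lif_subthreshold <- function(v0, drive_mV, a) {
  as.numeric(stats::filter((1 - a) * drive_mV, a, method = "recursive",
                           init = v0))
}

#' Simulate passive (subthreshold) voltage responses
#'
#' Generates sweeps from the RC closed form
#' `V(t) = E_L + I R (1 - exp(-t/tau))` (with proper handling of step onset
#' and offset), adding i.i.d. Gaussian recording noise. Steps must be
#' hyperpolarising or zero; a passive model cannot produce the regenerative
#' response a depolarising step would demand.
#'
#' @param model A [passive_model()].
#' @param steps A [step_descriptor()] or list of them.
#' @param rate Sampling rate, Hz.
#' @param duration_s Sweep duration, seconds (default spans the step plus
#'   half a second of recovery).
#' @param seed RNG seed (restores the caller's RNG state).
#' @return List of [voltage_sweep()] objects with a `"truth"` attribute
#'   (model parameters).
#' @export
simulate_passive <- function(model, steps, rate = 50000, duration_s = NULL,
                             seed = NULL) {
  stopifnot(inherits(model, "passive_model"))
  if (inherits(steps, "step_descriptor")) steps <- list(steps)
  for (st in steps) {
    if (st$amplitude_pA > 0)
      stop("passive model refuses depolarising steps", call. = FALSE)
  }
  with_seed(seed, {
    sweeps <- lapply(seq_along(steps), function(k) {
      st <- steps[[k]]
      dur <- if (is.null(duration_s)) st$onset_s + st$duration_s + 0.5
             else duration_s
      n <- round(dur * rate)
      t_ms <- (seq_len(n) - 1) / rate * 1000
      on_ms <- st$onset_s * 1000
      off_ms <- (st$onset_s + st$duration_s) * 1000
      v_base <- model$E_L + st$baseline_pA * model$R_in / 1000
      v_inf <- v_base + st$amplitude_pA * model$R_in / 1000
      v <- rep(v_base, n)
      on <- t_ms >= on_ms & t_ms < off_ms
      v[on] <- v_inf + (v_base - v_inf) * exp(-(t_ms[on] - on_ms) / model$tau_m)
      post <- t_ms >= off_ms
      if (any(post)) {
        v_off <- v_inf + (v_base - v_inf) * exp(-(off_ms - on_ms) / model$tau_m)
        v[post] <- v_base + (v_off - v_base) *
          exp(-(t_ms[post] - off_ms) / model$tau_m)
      }
      if (model$noise_sd > 0) v <- v + stats::rnorm(n, 0, model$noise_sd)
      voltage_sweep(v, st, sampling_rate = rate,
                    sweep_id = sprintf("passive_%02d", k))
    })
    attr(sweeps, "truth") <- list(E_L = model$E_L, R_in = model$R_in,
                                  tau_m = model$tau_m,
                                  noise_sd = model$noise_sd)
    sweeps
  })
}

ap_template <- function(model, dt_ms) {
  n_rise <- max(1L, round(model$ap_rise_ms / dt_ms))
  n_fall <- max(1L, round(model$ap_fall_ms / dt_ms))
  n_ref <- max(round(model$t_ref / dt_ms), n_rise + n_fall)
  t <- (0:(n_ref - 1L)) * dt_ms
  rise_ms <- n_rise * dt_ms
  fall_ms <- n_fall * dt_ms
  ref_ms <- n_ref * dt_ms
  peak <- model$V_T + model$ap_peak_amp
  v <- numeric(n_ref)
  seg1 <- t < rise_ms
  v[seg1] <- model$V_T + model$ap_peak_amp * t[seg1] / rise_ms
  seg2 <- !seg1 & t < rise_ms + fall_ms
  v[seg2] <- peak - (peak - model$V_T) * (t[seg2] - rise_ms) / fall_ms
  seg3 <- t >= rise_ms + fall_ms
  if (any(seg3)) {
    tail_ms <- ref_ms - rise_ms - fall_ms
    v[seg3] <- model$V_T + (model$V_reset - model$V_T) *
      (t[seg3] - rise_ms - fall_ms) / tail_ms
  }
  list(values = v, n_ref = n_ref, rise_ms = rise_ms, fall_ms = fall_ms,
       ref_ms = ref_ms, half_width_ms = (rise_ms + fall_ms) / 2)
}

#' Simulate spiking responses to current steps
#'
#' Leaky integrate-and-fire dynamics integrated exactly at the sampling grid
#' (exponential-Euler update, exact for piecewise-constant current). When the
#' membrane reaches the threshold `V_T` — compared with a small numerical
#' tolerance `v_tol` so that a step whose steady state sits exactly at
#' threshold fires in the long-step limit — the piecewise-linear AP template
#' is painted into the trace, the membrane is clamped for the refractory
#' period, and integration resumes from `V_reset`. Spike counts are
#' deterministic given the model (recording noise is added to the emitted
#' samples only).
#'
#' @param model A [spiking_model()].
#' @param steps A [step_descriptor()] or list of them.
#' @param rate Sampling rate, Hz.
#' @param duration_s Sweep duration, seconds.
#' @param v_tol Numerical tolerance (mV) for the threshold comparison.
#' @param seed RNG seed.
#' @return List of [voltage_sweep()] objects; attribute `"truth"` holds the
#'   model, effective template timings, per-sweep spike sample indices and
#'   closed-form AP features (threshold `V_T`, amplitude `ap_peak_amp`,
#'   half-width `(rise + fall)/2` on the quantised grid).
#' @export
simulate_spiking <- function(model, steps, rate = 50000, duration_s = NULL,
                             v_tol = 1e-6, seed = NULL) {
  stopifnot(inherits(model, "spiking_model"))
  if (inherits(steps, "step_descriptor")) steps <- list(steps)
  dt_ms <- 1000 / rate
  a <- exp(-dt_ms / model$tau_m)
  tpl <- ap_template(model, dt_ms)
  with_seed(seed, {
    spike_idx_all <- vector("list", length(steps))
    sweeps <- lapply(seq_along(steps), function(k) {
      st <- steps[[k]]
      dur <- if (is.null(duration_s)) st$onset_s + st$duration_s + 0.2
             else duration_s
      n <- round(dur * rate)
      i_pA <- step_current(st, n, rate)
      drive <- model$E_L + i_pA * model$R_in / 1000
      v <- numeric(n)
      spikes <- integer(0)
      pos <- 1L
      v0 <- model$E_L + st$baseline_pA * model$R_in / 1000
      v[1] <- v0
      while (pos <= n) {
        seg <- lif_subthreshold(v0, drive[pos:n], a)
        hit <- which(seg >= model$V_T - v_tol)
        if (!length(hit)) {
          v[pos:n] <- seg
          break
        }
        s <- pos + hit[1] - 1L
        if (hit[1] > 1L) v[pos:(s - 1L)] <- seg[seq_len(hit[1] - 1L)]
        spikes <- c(spikes, s)
        last <- min(s + tpl$n_ref - 1L, n)
        v[s:last] <- tpl$values[seq_len(last - s + 1L)]
        pos <- s + tpl$n_ref
        v0 <- model$V_reset
      }
      spike_idx_all[[k]] <<- spikes
      if (model$noise_sd > 0) v <- v + stats::rnorm(n, 0, model$noise_sd)
      voltage_sweep(v, st, sampling_rate = rate,
                    sweep_id = sprintf("step_%+05.0fpA_%02d",
                                       st$amplitude_pA, k))
    })
    attr(sweeps, "truth") <- list(
      model = model, rate = rate,
      rise_ms = tpl$rise_ms, fall_ms = tpl$fall_ms, ref_ms = tpl$ref_ms,
      threshold_mV = model$V_T, amplitude_mV = model$ap_peak_amp,
      half_width_ms = tpl$half_width_ms,
      spike_idx = spike_idx_all,
      n_spikes = lengths(spike_idx_all))
    sweeps
  })
}

#' Standard current-step grid
#'
#' The 1-s step protocol: amplitudes from `from` to `to` in `by` increments.
#'
#' @param from,to,by Step amplitudes in pA (defaults -100 to +500 by 25).
#' @param onset_s,duration_s Step timing in seconds.
#' @return List of [step_descriptor()] objects.
#' @export
step_grid <- function(from = -100, to = 500, by = 25, onset_s = 0.1,
                      duration_s = 1) {
  lapply(seq(from, to, by = by), function(amp)
    step_descriptor(0, amp, onset_s, duration_s))
}

#' Simulate the escalating 2-ms single-AP protocol
#'
#' Short depolarising pulses increasing by `increment_pA` until a sweep
#' contains exactly one action potential. If the ceiling is reached without
#' one, the result carries a protocol-failure flag rather than an error.
#'
#' @param model A [spiking_model()].
#' @param start_pA First pulse amplitude, pA.
#' @param increment_pA Escalation step, pA (> 0).
#' @param pulse_ms Pulse duration, ms (default 2).
#' @param ceiling_pA Largest amplitude attempted.
#' @param rate Sampling rate, Hz.
#' @param seed RNG seed.
#' @return List with `sweeps`, `amplitudes_pA`, `first_single_ap` (index of
#'   the first sweep with exactly one AP, or `NA`), `protocol_failed` flag,
#'   and the per-sweep ground-truth spike counts.
#' @export
simulate_single_ap_protocol <- function(model, start_pA = 25,
                                        increment_pA = 25, pulse_ms = 2,
                                        ceiling_pA = 5000, rate = 50000,
                                        seed = NULL) {
  if (increment_pA <= 0) stop("increment must be positive", call. = FALSE)
  amps <- seq(start_pA, ceiling_pA, by = increment_pA)
  sweeps <- list()
  counts <- integer(0)
  first_single <- NA_integer_
  for (k in seq_along(amps)) {
    st <- step_descriptor(0, amps[k], onset_s = 0.01,
                          duration_s = pulse_ms / 1000)
    sw <- simulate_spiking(model, st, rate = rate, duration_s = 0.05,
                           seed = if (is.null(seed)) NULL else seed + k)
    counts[k] <- attr(sw, "truth")$n_spikes[1]
    sweeps[[k]] <- sw[[1]]
    if (counts[k] >= 1) {
      if (counts[k] == 1) first_single <- k
      break
    }
  }
  list(sweeps = sweeps, amplitudes_pA = amps[seq_along(sweeps)],
       spike_counts = counts,
       first_single_ap = first_single,
       protocol_failed = is.na(first_single))
}

#' Simulate a trapezoidal AIS fluorescence profile
#'
#' Intensity is `baseline` outside the AIS, rises linearly over `edge_um`
#' to `f_max`, holds for `plateau_um`, and falls linearly over `edge_um`.
#' With zero baseline the 0.33-of-maximum boundary rule has analytic
#' crossings at `start_um + 0.33 * edge_um` and
#' `start_um + edge_um + plateau_um + 0.67 * edge_um`, giving a ground-truth
#' length of `plateau_um + 1.34 * edge_um`.
#'
#' @param start_um Arc-length position where the rising edge begins, µm.
#' @param plateau_um Plateau length, µm.
#' @param edge_um Rise/fall edge length, µm (0 gives a rectangle).
#' @param f_max Plateau intensity (arbitrary units).
#' @param baseline Background intensity.
#' @param noise_sd Additive Gaussian noise SD (intensity units).
#' @param dx_um Sampling interval along the trace, µm.
#' @param tail_um Flat tail beyond the falling edge, µm (defaults to
#'   `start_um`, giving symmetric flanks).
#' @param threshold_fraction Fraction used for the ground-truth crossings.
#' @param seed RNG seed.
#' @return A [fluorescence_profile()] with attribute `"truth"` (analytic
#'   start, end and length for the baseline-subtracted profile).
#' @export
simulate_ais_profile <- function(start_um = 5, plateau_um = 20, edge_um = 1,
                                 f_max = 1000, baseline = 0, noise_sd = 0,
                                 dx_um = 0.1, tail_um = start_um,
                                 threshold_fraction = 0.33, seed = NULL) {
  stopifnot(start_um >= 0, plateau_um > 0, edge_um >= 0, f_max > 0,
            dx_um > 0, noise_sd >= 0)
  total <- start_um + 2 * edge_um + plateau_um + tail_um
  x <- seq(0, total, by = dx_um)
  shape <- numeric(length(x))
  r0 <- start_um; r1 <- start_um + edge_um
  p1 <- r1 + plateau_um; f1 <- p1 + edge_um
  if (edge_um > 0) {
    idx <- x >= r0 & x < r1
    shape[idx] <- (x[idx] - r0) / edge_um
    idx <- x >= p1 & x < f1
    shape[idx] <- 1 - (x[idx] - p1) / edge_um
  }
  shape[x >= r1 & x < p1] <- 1
  if (edge_um == 0) shape[x >= r0 & x < p1] <- 1
  y <- baseline + f_max * shape
  y <- with_seed(seed, y + if (noise_sd > 0)
    stats::rnorm(length(x), 0, noise_sd) else 0)
  prof <- fluorescence_profile(x, pmax(y, 0), source = "synthetic")
  th <- threshold_fraction
  attr(prof, "truth") <- list(
    start_um = r0 + th * edge_um,
    end_um = p1 + (1 - th) * edge_um,
    length_um = plateau_um + 2 * (1 - th) * edge_um,
    f_max = f_max, baseline = baseline,
    threshold_fraction = th)
  prof
}

#' Cohort specification for the hierarchical generator
#'
#' Describes a balanced factorial cohort: `n_per_group_sex` animals in each
#' Group × Sex cell (default 3, i.e. 12 animals — six stroke and six sham,
#' evenly split by sex) and `cells_per_stratum` recorded cells per
#' Hemisphere × Layer stratum within each animal (default 2, i.e. 8 cells
#' per animal). Outcomes are generated on the declared scale as
#' `design %*% beta + animal intercept + animal hemisphere-slope + residual`.
#'
#' @param outcome_name Outcome label carried into the cell table.
#' @param intercept Intercept of the linear predictor (link scale).
#' @param effects Named numeric vector of non-intercept coefficients on
#'   `model.matrix(~ group * hemisphere * sex * layer)` term names (e.g.
#'   `c(groupstroke = -0.7)`); unnamed terms are zero.
#' @param scale `"natural"` (identity) or `"log"` (outcome is
#'   `exp(linear predictor)`).
#' @param n_per_group_sex Animals per Group × Sex cell.
#' @param cells_per_stratum Cells per Hemisphere × Layer stratum per animal.
#' @param sd_intercept,sd_slope Animal-level random-effect SDs (link scale).
#' @param cor_re Correlation between intercept and hemisphere slope.
#' @param sd_resid Residual SD (link scale).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(outcome_name = "ap_threshold_mV", intercept = -44,
                        effects = c(groupstroke = 0), scale = "natural",
                        n_per_group_sex = 3, cells_per_stratum = 2,
                        sd_intercept = 1, sd_slope = 0.5, cor_re = 0,
                        sd_resid = 2) {
  scale <- match.arg(scale, c("natural", "log"))
  if (sd_intercept < 0 || sd_slope < 0 || sd_resid < 0)
    stop("random-effect and residual SDs must be non-negative", call. = FALSE)
  if (abs(cor_re) > 1) stop("correlation must lie in [-1, 1]", call. = FALSE)
  structure(list(outcome_name = outcome_name, intercept = intercept,
                 effects = effects, scale = scale,
                 n_per_group_sex = n_per_group_sex,
                 cells_per_stratum = cells_per_stratum,
                 sd_intercept = sd_intercept, sd_slope = sd_slope,
                 cor_re = cor_re, sd_resid = sd_resid),
            class = "cohort_spec")
}

#' Simulate a hierarchical factorial cohort
#'
#' @param spec A [cohort_spec()].
#' @param seed RNG seed.
#' @return A tibble cell table (columns `animal_id`, `group`, `hemisphere`,
#'   `layer`, `sex`, `gfp`, `outcome_name`, `outcome_value`) with attribute
#'   `"truth"`: the full named coefficient vector on the link scale, the
#'   random-effect SDs/correlation, residual SD and scale.
#' @export
simulate_cohort <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  gs <- expand.grid(group = cell_factor_levels$group,
                    sex = cell_factor_levels$sex,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  animals <- do.call(rbind, lapply(seq_len(nrow(gs)), function(i)
    data.frame(animal_id = sprintf("%s_%s_%d", gs$group[i], gs$sex[i],
                                   seq_len(spec$n_per_group_sex)),
               group = gs$group[i], sex = gs$sex[i])))
  strat <- expand.grid(hemisphere = cell_factor_levels$hemisphere,
                       layer = cell_factor_levels$layer,
                       cell = seq_len(spec$cells_per_stratum),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  dat <- merge(animals, strat, by = NULL)
  dat <- dat[order(dat$animal_id, dat$hemisphere, dat$layer, dat$cell), ]
  for (f in c("group", "hemisphere", "layer", "sex"))
    dat[[f]] <- factor(dat[[f]], levels = cell_factor_levels[[f]])
  X <- stats::model.matrix(~ group * hemisphere * sex * layer, dat)
  beta <- stats::setNames(numeric(ncol(X)), colnames(X))
  beta["(Intercept)"] <- spec$intercept
  if (length(spec$effects)) {
    unknown <- setdiff(names(spec$effects), colnames(X))
    if (length(unknown))
      stop("unknown effect term(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    beta[names(spec$effects)] <- spec$effects
  }
  with_seed(seed, {
    n_an <- nrow(animals)
    z1 <- stats::rnorm(n_an)
    z2 <- spec$cor_re * z1 + sqrt(1 - spec$cor_re^2) * stats::rnorm(n_an)
    u1 <- stats::setNames(spec$sd_intercept * z1, animals$animal_id)
    u2 <- stats::setNames(spec$sd_slope * z2, animals$animal_id)
    ipsi <- as.numeric(dat$hemisphere == "ipsilesional")
    eta <- as.vector(X %*% beta) + unname(u1[dat$animal_id]) +
      unname(u2[dat$animal_id]) * ipsi +
      stats::rnorm(nrow(dat), 0, spec$sd_resid)
    val <- if (spec$scale == "log") exp(eta) else eta
    out <- tibble::tibble(
      animal_id = dat$animal_id, group = dat$group,
      hemisphere = dat$hemisphere, layer = dat$layer, sex = dat$sex,
      gfp = factor(rep_len(c("positive", "negative"), nrow(dat)),
                   levels = cell_factor_levels$gfp),
      outcome_name = spec$outcome_name, outcome_value = val)
    attr(out, "truth") <- list(beta = beta, sd_intercept = spec$sd_intercept,
                               sd_slope = spec$sd_slope, cor_re = spec$cor_re,
                               sd_resid = spec$sd_resid, scale = spec$scale,
                               random_intercepts = u1, random_slopes = u2)
    out
  })
}

#' Simulate serial lesion-section areas from a known volume
#'
#' Inverse of [lesion_volume()]: distributes the per-series area implied by
#' `true_volume_mm3` across `n_sections` with an elliptical axial profile and
#' seeded multiplicative jitter, rescaled so the recomputed volume equals the
#' truth exactly.
#'
#' @param true_volume_mm3 Target total lesion volume, mm³.
#' @param n_sections Number of measured sections.
#' @param thickness_um Section thickness, µm.
#' @param series_factor Section-series sampling factor.
#' @param jitter_sd Log-normal jitter SD on the axial profile.
#' @param seed RNG seed.
#' @return A [lesion_series()] with attribute `"truth"` (the target volume).
#' @export
simulate_lesion_sections <- function(true_volume_mm3, n_sections,
                                     thickness_um = 30, series_factor = 3,
                                     jitter_sd = 0.1, seed = NULL) {
  stopifnot(true_volume_mm3 >= 0, n_sections >= 0)
  if (n_sections == 0 || true_volume_mm3 == 0) {
    out <- lesion_series(numeric(n_sections), thickness_um, series_factor)
    attr(out, "truth") <- list(volume_mm3 = true_volume_mm3 * (n_sections > 0))
    return(out)
  }
  target_um2 <- true_volume_mm3 * 1e9 / (thickness_um * series_factor)
  xs <- seq(-1, 1, length.out = n_sections + 2)[2:(n_sections + 1)]
  shape <- sqrt(pmax(1 - xs^2, 0))
  shape <- with_seed(seed,
    shape * exp(stats::rnorm(n_sections, 0, jitter_sd)))
  areas <- shape / sum(shape) * target_um2
  out <- lesion_series(areas, thickness_um, series_factor)
  attr(out, "truth") <- list(volume_mm3 = true_volume_mm3)
  out
}
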