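#' Default run configuration
#'
#' Every tunable of the pipeline with its documented default. Values are
#' grouped by stage; [read_config()] overlays a YAML file onto these defaults
#' and rejects unknown keys.
#'
#' @section Parameters:
#' \describe{
#'   \item{sampling_rate_hz}{Acquisition rate for simulated sweeps (50000).}
#'   \item{dvdt_threshold_v_per_s}{dV/dt criterion defining AP threshold (10).}
#'   \item{threshold_search_window_ms}{Backward search window from the AP
#'     peak for the dV/dt crossing (5).}
#'   \item{peak_floor_mV}{Voltage floor for peak candidacy in spike
#'     detection (0).}
#'   \item{min_peak_separation_ms}{Refractory guard between detected
#'     peaks (1).}
#'   \item{rmp_window_ms}{Pre-stimulus baseline window for the resting
#'     membrane potential (100).}
#'   \item{steady_state_window_ms}{Final window of each 1-s step used for the
#'     steady-state voltage (100).}
#'   \item{tau_fit_skip_samples}{Samples skipped after step onset before the
#'     exponential fit (2, pipette transient).}
#'   \item{tau_fit_n_tau}{Fit window length in estimated time constants (5).}
#'   \item{ais_threshold_fraction}{Fraction of maximum fluorescence defining
#'     AIS boundaries (0.33).}
#'   \item{ais_smooth_window_um}{Moving-average window before boundary
#'     detection (1).}
#'   \item{ais_baseline_flank_fraction}{Fraction of samples at each profile
#'     end used for the median baseline (0.1).}
#'   \item{profile_spacing_um}{Arc-length spacing when sampling profiles from
#'     images (0.1).}
#'   \item{lesion_thickness_um}{Section thickness (30).}
#'   \item{lesion_series_factor}{Sampling series factor (3: every third
#'     section).}
#'   \item{n_boot}{Bootstrap resamples for estimation statistics (5000).}
#'   \item{ci_level}{Confidence/credible level for estimation statistics
#'     (0.95).}
#'   \item{boot_method}{Bootstrap interval type, `percentile` or `bca`.}
#'   \item{max_freq_definition}{`mean_rate` (whole-step count over 1 s) or
#'     `inv_min_isi`.}
#'   \item{chains, iterations, warmup}{MCMC defaults for tests-scale runs
#'     (4, 2000, 500); the publication-scale protocol (4, 50000, 10000) is a
#'     config choice.}
#'   \item{seed}{Default RNG seed (1).}
#' }
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    sampling_rate_hz = 50000,
    dvdt_threshold_v_per_s = 10,
    threshold_search_window_ms = 5,
    peak_floor_mV = 0,
    min_peak_separation_ms = 1,
    rmp_window_ms = 100,
    steady_state_window_ms = 100,
    tau_fit_skip_samples = 2,
    tau_fit_n_tau = 5,
    ais_threshold_fraction = 0.33,
    ais_smooth_window_um = 1,
    ais_baseline_flank_fraction = 0.1,
    profile_spacing_um = 0.1,
    lesion_thickness_um = 30,
    lesion_series_factor = 3,
    n_boot = 5000,
    ci_level = 0.95,
    boot_method = "percentile",
    max_freq_definition = "mean_rate",
    chains = 4,
    iterations = 2000,
    warmup = 500,
    seed = 1
  )
}

#' Read a run configuration file
#'
#' Overlays a YAML key-value file onto [default_config()]. Keys not present
#' in the defaults are an error (typo guard).
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return Named list of configuration values.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- yaml::read_yaml(path)
  if (is.null(user)) return(cfg)
  unknown <- setdiff(names(user), names(cfg))
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(user)] <- user
  cfg
}
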