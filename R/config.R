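#' Physiological parameters for one experimental condition
#'
#' Bundles the generative parameters that drive one condition (rest/control
#' or task) of the synthetic cohort. Units follow field conventions:
#' heart rate in beats/min, variability in ms, electrodermal level in
#' microsiemens (uS), breathing rate in cycles/min.
#'
#' @param mean_hr Mean heart rate (beats/min).
#' @param hrv_sdnn Target standard deviation of inter-beat intervals (ms).
#'   Respiratory sinus arrhythmia contributes part of this; the remainder is
#'   white beat-to-beat variability.
#' @param rsa_gain Peak-to-trough modulation of the heart period within one
#'   breath cycle (ms).
#' @param breathing_rate Breathing rate (cycles/min).
#' @param breath_jitter Relative standard deviation of breath-cycle duration
#'   (fraction of the mean cycle).
#' @param insp_frac Fraction of a breath cycle spent in inspiration.
#' @param breath_amp Peak-to-trough respiration amplitude (arbitrary units).
#' @param eda_tonic_level Mean tonic skin-conductance level (uS).
#' @param eda_tonic_drift_sd Standard deviation of the tonic random-walk
#'   drift (uS per minute).
#' @param scr_rate Rate of non-specific skin-conductance responses
#'   (events/min).
#' @param scr_amp_mean Mean SCR amplitude (uS); amplitudes are gamma
#'   distributed with shape 2.
#' @param scr_min_spacing Minimum spacing between SCR events (s); a short
#'   physiological refractory period.
#' @param noise_sd Named list of additive white-noise standard deviations per
#'   channel: `ecg` (mV), `eda` (uS), `resp` (units).
#'
#' @return An object of class `sim_params` (named list).
#' @export
sim_params <- function(mean_hr = 70,
                       hrv_sdnn = 50,
                       rsa_gain = 60,
                       breathing_rate = 14,
                       breath_jitter = 0.05,
                       insp_frac = 0.45,
                       breath_amp = 1,
                       eda_tonic_level = 5,
                       eda_tonic_drift_sd = 0.1,
                       scr_rate = 3,
                       scr_amp_mean = 0.3,
                       scr_min_spacing = 1,
                       noise_sd = list(ecg = 0.01, eda = 0.005, resp = 0.02)) {
  p <- list(mean_hr = mean_hr, hrv_sdnn = hrv_sdnn, rsa_gain = rsa_gain,
            breathing_rate = breathing_rate, breath_jitter = breath_jitter,
            insp_frac = insp_frac, breath_amp = breath_amp,
            eda_tonic_level = eda_tonic_level,
            eda_tonic_drift_sd = eda_tonic_drift_sd,
            scr_rate = scr_rate, scr_amp_mean = scr_amp_mean,
            scr_min_spacing = scr_min_spacing, noise_sd = noise_sd)
  class(p) <- "sim_params"
  validate_sim_params(p)
  p
}

validate_sim_params <- function(p) {
  stopifnot(is.list(p))
  if (!is.numeric(p$mean_hr) || p$mean_hr <= 0)
    stop("invalid config: mean_hr must be > 0", call. = FALSE)
  if (p$breathing_rate <= 0)
    stop("invalid config: breathing_rate must be > 0", call. = FALSE)
  if (p$scr_rate < 0)
    stop("invalid config: scr_rate must be >= 0", call. = FALSE)
  if (p$scr_amp_mean <= 0)
    stop("invalid config: scr_amp_mean must be > 0", call. = FALSE)
  if (p$hrv_sdnn < 0 || p$rsa_gain < 0)
    stop("invalid config: hrv_sdnn and rsa_gain must be >= 0", call. = FALSE)
  if (p$insp_frac <= 0 || p$insp_frac >= 1)
    stop("invalid config: insp_frac must be in (0, 1)", call. = FALSE)
  invisible(p)
}

#' Task-condition parameters shifted relative to a control condition
#'
#' Applies the default task-vs-control effect structure: the task raises mean
#' heart rate (shorter inter-beat intervals), tonic electrodermal level,
#' non-specific SCR rate and breathing rate. Effect magnitudes are cohort
#' defaults and can be overridden.
#'
#' @param base `sim_params` for the control condition.
#' @param d_hr Heart-rate increase (beats/min).
#' @param d_tonic Tonic EDA increase (uS).
#' @param d_scr_rate SCR-rate increase (events/min).
#' @param d_br Breathing-rate increase (cycles/min).
#' @return A `sim_params` object.
#' @export
task_params <- function(base = sim_params(), d_hr = 7, d_tonic = 0.5,
                        d_scr_rate = 5, d_br = 2) {
  p <- base
  p$mean_hr <- base$mean_hr + d_hr
  p$eda_tonic_level <- base$eda_tonic_level + d_tonic
  p$scr_rate <- base$scr_rate + d_scr_rate
  p$breathing_rate <- base$breathing_rate + d_br
  validate_sim_params(p)
  p
}

#' Simulation configuration for a synthetic cohort
#'
#' Describes the recording protocol (a rest baseline followed by a task-phase
#' drive, both sampled at `sampling_rate`), the two condition parameter sets,
#' and the between-/within-subject variability of the main physiological
#' parameters. The defaults emulate the study protocol: 5-min baseline,
#' 20-min drive, 1000 Hz.
#'
#' @param sampling_rate Sampling rate in Hz for all three channels.
#' @param baseline_duration Baseline duration in seconds.
#' @param driving_duration Task-phase duration in seconds.
#' @param control_params,task_params `sim_params` for the two conditions.
#'   Both groups share the control parameters during the baseline.
#' @param between_sd Named numeric vector of between-subject standard
#'   deviations added once per subject to both phases.
#' @param within_sd Named numeric vector of within-subject (per phase)
#'   standard deviations; this is the session-to-session noise that limits
#'   how well baseline-delta features isolate the condition effect.
#' @param seed Integer cohort-level seed; per-subject substreams are derived
#'   deterministically from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(sampling_rate = 1000,
                       baseline_duration = 300,
                       driving_duration = 1200,
                       control_params = sim_params(),
                       task_params = physiowork::task_params(control_params),
                       between_sd = c(mean_hr = 7, hrv_sdnn = 10,
                                      rsa_gain = 15, breathing_rate = 1.5,
                                      breath_amp = 0.15,
                                      eda_tonic_level = 1.5, scr_rate = 1.5),
                       within_sd = c(mean_hr = 3, hrv_sdnn = 8,
                                     rsa_gain = 10, breathing_rate = 1.5,
                                     breath_amp = 0.05,
                                     eda_tonic_level = 0.4, scr_rate = 2),
                       seed = 1L) {
  if (sampling_rate <= 0) stop("invalid config: sampling_rate must be > 0",
                               call. = FALSE)
  if (baseline_duration <= 0 || driving_duration <= 0)
    stop("invalid config: durations must be > 0", call. = FALSE)
  validate_sim_params(control_params)
  validate_sim_params(task_params)
  cfg <- list(sampling_rate = sampling_rate,
              baseline_duration = baseline_duration,
              driving_duration = driving_duration,
              control_params = control_params,
              task_params = task_params,
              between_sd = between_sd,
              within_sd = within_sd,
              seed = as.integer(seed))
  class(cfg) <- "sim_config"
  cfg
}

# Perturb a sim_params with named gaussian offsets; rates and levels are kept
# in their valid ranges.
perturb_params <- function(p, sd_vec) {
  if (is.null(sd_vec) || length(sd_vec) == 0) return(p)
  for (nm in names(sd_vec)) {
    if (sd_vec[[nm]] <= 0) next
    p[[nm]] <- p[[nm]] + stats::rnorm(1, 0, sd_vec[[nm]])
  }
  p$mean_hr <- max(p$mean_hr, 40)
  p$hrv_sdnn <- max(p$hrv_sdnn, 0)
  p$rsa_gain <- max(p$rsa_gain, 0)
  p$breathing_rate <- max(p$breathing_rate, 6)
  p$breath_amp <- max(p$breath_amp, 0.2)
  p$eda_tonic_level <- max(p$eda_tonic_level, 0.5)
  p$scr_rate <- max(p$scr_rate, 0)
  p
}
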