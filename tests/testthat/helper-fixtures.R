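# Reduced-scale study configurations for unit tests: short phases keep the
# per-subject cost low while preserving every pipeline stage.

tiny_config <- function(seed = 1, baseline = 60, driving = 120, ...) {
  sim_config(baseline_duration = baseline, driving_duration = driving,
             seed = seed, ...)
}

# Zero-noise configuration with well-separated, comfortably sized SCRs so
# that detector round-trips against ground truth are identifiable.
noiseless_config <- function(seed = 1, baseline = 60, driving = 240) {
  quiet <- function(p) {
    p$noise_sd <- list(ecg = 0, eda = 0, resp = 0)
    p$scr_min_spacing <- 5
    p$scr_rate <- 4
    p$scr_amp_mean <- 0.4
    p$eda_tonic_drift_sd <- 0.05
    p
  }
  ctrl <- quiet(sim_params())
  sim_config(baseline_duration = baseline, driving_duration = driving,
             control_params = ctrl, task_params = task_params(ctrl),
             between_sd = c(mean_hr = 5), within_sd = c(mean_hr = 2),
             seed = seed)
}

# Null configuration: task parameters identical to control.
null_config <- function(seed = 1, baseline = 60, driving = 60) {
  ctrl <- sim_params()
  sim_config(baseline_duration = baseline, driving_duration = driving,
             control_params = ctrl, task_params = ctrl, seed = seed)
}
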