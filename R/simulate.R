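#' Simulate breath cycles and a respiration waveform
#'
#' Generates a sequence of breath cycles (inspiration followed by
#' expiration) with lognormal-free gaussian jitter on cycle duration, and a
#' piecewise-cosine chest-expansion waveform whose trough marks the cycle
#' onset (inspiration start) and whose peak-to-trough excursion per cycle is
#' the cycle amplitude.
#'
#' @param params A [sim_params()] object.
#' @param duration Duration in seconds (> 0).
#' @param fs Sampling rate of the returned waveform (Hz).
#' @return A list with `onsets` (cycle onset times, s), `insp` and `exp`
#'   (per-cycle inspiration/expiration durations, s), `amplitudes`
#'   (peak-to-trough, units) and `resp` (waveform of length
#'   `round(duration * fs)`).
#' @export
simulate_breath_cycles <- function(params, duration, fs = 1000) {
  validate_sim_params(params)
  if (!is.numeric(duration) || duration <= 0)
    stop("invalid config: duration must be > 0", call. = FALSE)
  mean_cycle <- 60 / params$breathing_rate
  # draw enough cycles to cover the duration, then trim
  n_guess <- ceiling(duration / mean_cycle * 1.5) + 5
  durs <- stats::rnorm(n_guess, mean_cycle, params$breath_jitter * mean_cycle)
  durs <- pmax(durs, 0.25 * mean_cycle)
  onsets <- c(0, cumsum(durs))
  keep <- onsets < duration
  onsets <- onsets[keep]
  durs <- durs[seq_along(onsets)]
  insp <- durs * params$insp_frac
  amp <- pmax(params$breath_amp *
                (1 + stats::rnorm(length(durs), 0, 0.05)), 0.05)

  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  cyc <- findInterval(t, onsets)            # cycle index per sample (>= 1)
  rel <- t - onsets[cyc]
  insp_c <- insp[cyc]; durs_c <- durs[cyc]
  # phase 0..0.5 over inspiration (trough -> peak), 0.5..1 over expiration
  ph <- 0.5 * rel / insp_c
  ex <- rel >= insp_c
  ph[ex] <- 0.5 + 0.5 * (rel[ex] - insp_c[ex]) / (durs_c[ex] - insp_c[ex])
  wave <- -cos(2 * pi * ph) * amp[cyc] / 2
  wave <- wave + stats::rnorm(n, 0, params$noise_sd$resp)
  list(onsets = onsets, insp = insp, exp = durs - insp,
       amplitudes = amp, resp = wave)
}

#' Simulate an R-peak time series with respiratory coupling
#'
#' Heart periods are modulated sinusoidally within each breath cycle
#' (respiratory sinus arrhythmia): the period is shortest around the end of
#' inspiration and longest during expiration, with a peak-to-trough range of
#' `rsa_gain` ms. White gaussian beat-to-beat variability is added so the
#' total inter-beat-interval standard deviation approximates `hrv_sdnn`.
#'
#' @param params A [sim_params()] object.
#' @param breaths Breath cycles from [simulate_breath_cycles()] covering the
#'   duration (may be `NULL` when `rsa_gain` is 0).
#' @param duration Duration in seconds.
#' @return Numeric vector of R-peak times (s), strictly increasing.
#' @export
simulate_ibi_series <- function(params, breaths, duration) {
  validate_sim_params(params)
  if (duration <= 0) stop("invalid config: duration must be > 0", call. = FALSE)
  base_ibi <- 60000 / params$mean_hr              # ms
  sd_rsa <- params$rsa_gain / (2 * sqrt(2))       # sd of a sinusoid of range gain
  sd_white <- sqrt(max(params$hrv_sdnn^2 - sd_rsa^2, 0))

  rsa_mod <- function(tt) {
    if (params$rsa_gain == 0 || is.null(breaths)) return(0)
    cyc <- findInterval(tt, breaths$onsets)
    if (cyc < 1) return(0)
    onset <- breaths$onsets[cyc]
    cycle_dur <- if (cyc < length(breaths$onsets))
      breaths$onsets[cyc + 1] - onset
    else breaths$insp[cyc] + breaths$exp[cyc]
    ph <- (tt - onset) / cycle_dur
    # heart period dips (shorter IBI) during inspiration, peaks in expiration
    -(params$rsa_gain / 2) * cos(2 * pi * (ph - params$insp_frac))
  }

  n_guess <- ceiling(duration / (base_ibi / 1000)) + 10
  noise <- stats::rnorm(n_guess, 0, sd_white)
  times <- numeric(n_guess)
  tcur <- 0.2 * base_ibi / 1000                   # first beat shortly after start
  k <- 0
  while (tcur < duration) {
    k <- k + 1
    if (k > n_guess) {                            # extend noise draws if needed
      noise <- c(noise, stats::rnorm(n_guess, 0, sd_white))
      n_guess <- length(noise)
    }
    times[k] <- tcur
    ibi <- base_ibi + rsa_mod(tcur) + noise[k]
    ibi <- max(ibi, 250)                          # physiological floor
    tcur <- tcur + ibi / 1000
  }
  times[seq_len(k)]
}

# Fixed QRS-like template: dominant R deflection with small Q/S dips.
qrs_template <- function(fs) {
  t <- seq(-0.05, 0.05, by = 1 / fs)
  r <- exp(-(t / 0.008)^2)                        # R wave, ~16 ms wide
  q <- -0.15 * exp(-((t + 0.025) / 0.01)^2)
  s <- -0.2 * exp(-((t - 0.025) / 0.01)^2)
  r + q + s
}

#' Render an ECG waveform from R-peak times
#'
#' Places a fixed QRS-like template (unit R amplitude, mV) at each peak time
#' and adds white gaussian noise. Morphological realism beyond the dominant
#' R deflection (P/T waves) is intentionally not modelled: the pipeline uses
#' the ECG only for R-peak detection.
#'
#' @param r_peak_times Strictly increasing R-peak times (s); may be empty.
#' @param duration Total duration (s).
#' @param fs Sampling rate (Hz).
#' @param noise_sd White-noise standard deviation (mV).
#' @return Numeric waveform of length `round(duration * fs)`.
#' @export
render_ecg <- function(r_peak_times, duration, fs = 1000, noise_sd = 0) {
  if (length(r_peak_times) > 1 && any(diff(r_peak_times) <= 0))
    stop("r_peak_times must be strictly increasing", call. = FALSE)
  n <- round(duration * fs)
  x <- numeric(n)
  tpl <- qrs_template(fs)
  half <- (length(tpl) - 1) / 2
  idx_peak <- round(r_peak_times * fs) + 1
  for (ip in idx_peak) {
    lo <- ip - half; hi <- ip + half
    sl <- max(lo, 1):min(hi, n)
    if (length(sl) == 0 || sl[1] > n) next
    x[sl] <- x[sl] + tpl[sl - lo + 1]
  }
  if (noise_sd > 0) x <- x + stats::rnorm(n, 0, noise_sd)
  x
}

# Bateman bi-exponential SCR kernel, peak normalised to 1.
bateman_kernel <- function(fs, tau_rise = 1, tau_decay = 4, t_max = 25) {
  t <- seq(0, t_max, by = 1 / fs)
  h <- exp(-t / tau_decay) - exp(-t / tau_rise)
  h / max(h)
}

#' Simulate an electrodermal activity channel
#'
#' The signal is the sum of a slowly drifting tonic level (random walk around
#' `eda_tonic_level`, smoothed), sparse skin-conductance responses placed at
#' Poisson event times with a refractory period (`scr_min_spacing`) and
#' bi-exponential (Bateman) shape with ~1 s rise and ~4 s decay, plus white
#' gaussian noise. Values are clipped at 0 uS.
#'
#' @param params A [sim_params()] object.
#' @param duration Duration (s).
#' @param fs Sampling rate (Hz).
#' @return List with `eda` (waveform), `tonic_trace` (noise-free tonic, same
#'   length), `scr_times` (event onset times, s) and `scr_amps` (amplitudes,
#'   uS).
#' @export
simulate_eda <- function(params, duration, fs = 1000) {
  validate_sim_params(params)
  if (duration <= 0) stop("invalid config: duration must be > 0", call. = FALSE)
  n <- round(duration * fs)

  # tonic drift: random walk at 1 Hz, linearly interpolated to fs
  n1 <- max(ceiling(duration), 2)
  step_sd <- params$eda_tonic_drift_sd / sqrt(60)  # uS per sqrt(s)
  walk <- cumsum(c(0, stats::rnorm(n1 - 1, 0, step_sd)))
  walk <- walk - mean(walk)
  tonic <- stats::approx(seq(0, duration, length.out = n1), walk + params$eda_tonic_level,
                         xout = (seq_len(n) - 1) / fs, rule = 2)$y

  # SCR events: Poisson with refractory spacing
  scr_times <- numeric(0)
  if (params$scr_rate > 0) {
    n_ev <- stats::rpois(1, params$scr_rate * duration / 60)
    if (n_ev > 0) {
      cand <- sort(stats::runif(n_ev, 0, max(duration - 5, duration * 0.8)))
      keep <- c(TRUE, diff(cand) >= params$scr_min_spacing)
      scr_times <- cand[keep]
    }
  }
  scr_amps <- if (length(scr_times))
    stats::rgamma(length(scr_times), shape = 2, scale = params$scr_amp_mean / 2)
  else numeric(0)

  phasic <- numeric(n)
  if (length(scr_times)) {
    ker <- bateman_kernel(fs)
    kl <- length(ker)
    for (i in seq_along(scr_times)) {
      i0 <- round(scr_times[i] * fs) + 1
      sl <- i0:min(i0 + kl - 1, n)
      phasic[sl] <- phasic[sl] + scr_amps[i] * ker[seq_along(sl)]
    }
  }
  eda <- tonic + phasic
  if (params$noise_sd$eda > 0) eda <- eda + stats::rnorm(n, 0, params$noise_sd$eda)
  eda <- pmax(eda, 0)
  list(eda = eda, tonic_trace = tonic, scr_times = scr_times,
       scr_amps = scr_amps)
}

# Simulate one protocol phase (all channels + truth) under given parameters.
simulate_phase <- function(params, duration, fs) {
  br <- simulate_breath_cycles(params, duration, fs)
  rpk <- simulate_ibi_series(params, br, duration)
  ecg <- render_ecg(rpk, duration, fs, params$noise_sd$ecg)
  eda <- simulate_eda(params, duration, fs)
  list(ecg = ecg, eda = eda$eda, resp = br$resp,
       truth = list(r_peak_times = rpk,
                    breath_onset_times = br$onsets,
                    insp = br$insp, expir = br$exp,
                    breath_amplitudes = br$amplitudes,
                    scr_event_times = eda$scr_times,
                    scr_amplitudes = eda$scr_amps,
                    tonic_trace = eda$tonic_trace))
}

# Deterministic 31-bit per-subject substream seed.
subject_seed <- function(cohort_seed, i) {
  as.integer((as.numeric(cohort_seed) * 1009 + 7919 * as.numeric(i)) %% 2147483647)
}

#' Simulate one subject's recording with ground truth
#'
#' The recording spans the baseline followed by the task (driving) phase.
#' The baseline is generated with control-condition parameters for both
#' groups; the driving phase uses the condition-specific parameters. Stable
#' subject traits (between-subject offsets) are shared by both phases, while
#' per-phase within-subject offsets model session-level physiological drift.
#'
#' @param config A [sim_config()] object.
#' @param condition `"control"` or `"task"`.
#' @param subject_id Identifier stored in the recording.
#' @param seed Optional integer overriding the substream seed derived from
#'   `config$seed` and `subject_id`.
#' @return A list with `recording` (class `raw_recording`: channels `ecg`,
#'   `eda`, `resp`, `sampling_rate`, `phases` data frame, `subject_id`,
#'   `condition`) and `truth` (per-phase ground truth, times relative to
#'   phase onset).
#' @export
simulate_subject <- function(config, condition = c("control", "task"),
                             subject_id = 1L, seed = NULL) {
  condition <- match.arg(condition)
  if (is.null(seed)) seed <- subject_seed(config$seed, subject_id)
  set.seed(seed)

  subj_off <- config$between_sd
  base_ctrl <- config$control_params
  base_cond <- if (condition == "task") config$task_params else config$control_params
  # one draw of subject traits, applied to both phases
  trait <- lapply(as.list(subj_off), function(s) stats::rnorm(1, 0, s))
  apply_off <- function(p, off) {
    for (nm in names(off)) p[[nm]] <- p[[nm]] + off[[nm]]
    perturb_params(p, c(none = 0))  # reuse range clipping only
  }
  p_base <- apply_off(base_ctrl, trait)
  p_drive <- apply_off(base_cond, trait)
  p_base <- perturb_params(p_base, config$within_sd)
  p_drive <- perturb_params(p_drive, config$within_sd)

  fs <- config$sampling_rate
  ph1 <- simulate_phase(p_base, config$baseline_duration, fs)
  ph2 <- simulate_phase(p_drive, config$driving_duration, fs)

  rec <- list(ecg = c(ph1$ecg, ph2$ecg),
              eda = c(ph1$eda, ph2$eda),
              resp = c(ph1$resp, ph2$resp),
              sampling_rate = fs,
              phases = data.frame(
                phase = c("baseline", "driving"),
                start = c(0, config$baseline_duration),
                end = c(config$baseline_duration,
                        config$baseline_duration + config$driving_duration)),
              subject_id = subject_id,
              condition = condition)
  class(rec) <- "raw_recording"
  list(recording = rec,
       truth = list(baseline = ph1$truth, driving = ph2$truth,
                    params = list(baseline = p_base, driving = p_drive)))
}

#' Simulate a balanced labelled cohort
#'
#' Generates `n` subjects with alternating condition labels (`task` first, so
#' `ceiling(n/2)` task and `floor(n/2)` control). Each subject is generated
#' from a deterministic substream of the cohort seed, so cohorts are
#' reproducible and a subject's data do not depend on cohort size.
#'
#' Full recordings at study scale are large (~36 MB per subject); pass `fun`
#' to map each subject to a reduced result (e.g. indicator tables) so raw
#' channels can be discarded as the cohort is generated.
#'
#' @param n Number of subjects (>= 2).
#' @param config A [sim_config()] object.
#' @param fun Optional function applied to each simulated subject (the list
#'   returned by [simulate_subject()]); when given, its results are returned
#'   instead of the raw subjects.
#' @param verbose Print per-subject progress.
#' @return List of length `n`: simulated subjects, or `fun` results.
#' @export
simulate_cohort <- function(n, config = sim_config(), fun = NULL,
                            verbose = FALSE) {
  if (n < 2) stop("a cohort needs at least 2 subjects", call. = FALSE)
  conditions <- rep(c("task", "control"), length.out = n)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    s <- simulate_subject(config, conditions[i], subject_id = i)
    out[[i]] <- if (is.null(fun)) s else fun(s)
    if (verbose) message(sprintf("subject %d/%d (%s) done", i, n, conditions[i]))
  }
  out
}
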