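#' The physiological indicator catalog
#'
#' Sixty-one indicators computed per analysis window: 10 electrodermal, 27
#' cardiac, 19 respiratory and 5 respiratory-sinus-arrhythmia indicators.
#' Cardiac and respiratory interval series share a 16-indicator core
#' (time-domain statistics, band powers and Poincare geometry); the cardiac
#' set adds histogram/normalised-power/vagal-sympathetic indices, the
#' respiratory set adds amplitude, approximate entropy and the long-term
#' detrended-fluctuation exponent.
#'
#' @return Data frame with columns `name` and `signal`
#'   (`EDA`/`ECG`/`RESP`/`RSA`), 61 rows.
#' @export
indicator_catalog <- function() {
  shared <- c("mean_rate", "mean", "median", "mad", "sd", "sdsd", "cv",
              "mcv", "rmssd", "cvsd", "lf", "hf", "lf_hf",
              "sd1", "sd2", "sd2_sd1")
  eda <- c("eda_mean", "eda_min", "eda_max", "eda_sd",
           "eda_tonic_mean", "eda_tonic_min", "eda_tonic_max", "eda_tonic_sd",
           "eda_scr_amp", "eda_scr_freq")
  ecg <- c(paste0("hrv_", shared),
           paste0("hrv_", c("pnn50", "pnn20", "tinn", "hti", "vhf", "lfn",
                            "hfn", "lnhf", "csi", "cvi", "csi_mod")))
  resp <- c(paste0("rrv_", shared),
            paste0("rrv_", c("amp_mean", "apen", "dfa2")))
  rsa <- c("rsa_mean", "rsa_mean_log", "rsa_sd", "rsa_norsa", "rsa_pb")
  data.frame(name = c(eda, ecg, resp, rsa),
             signal = rep(c("EDA", "ECG", "RESP", "RSA"),
                          c(length(eda), length(ecg), length(resp),
                            length(rsa))))
}

#' Time-domain statistics of an interval series
#'
#' Mean rate (events/min, 60000 divided by the mean interval in ms), mean,
#' median, mean absolute deviation about the median (or median absolute
#' deviation via `mad_type`), SD (n-1 denominator), SD of successive
#' differences (SDSD), coefficient of variation (SD/Mean), median-based CV
#' (MAD/Median), root-mean-square of successive differences (RMSSD) and
#' CVSD (RMSSD/Mean).
#'
#' @param series An [interval_series()].
#' @param mad_type `"mean_abs_dev"` (mean absolute deviation about the
#'   median, the default) or `"median_abs_dev"` (raw median absolute
#'   deviation).
#' @return Named numeric vector of 10 values; all `NA` with fewer than 3
#'   intervals.
#' @export
interval_time_stats <- function(series,
                                mad_type = c("mean_abs_dev", "median_abs_dev")) {
  mad_type <- match.arg(mad_type)
  iv <- series$intervals
  nm <- c("mean_rate", "mean", "median", "mad", "sd", "sdsd", "cv", "mcv",
          "rmssd", "cvsd")
  if (length(iv) < 3)
    return(stats::setNames(rep(NA_real_, length(nm)), nm))
  m <- mean(iv)
  md <- stats::median(iv)
  mad_v <- if (mad_type == "mean_abs_dev") mean(abs(iv - md))
           else stats::median(abs(iv - md))
  d <- diff(iv)
  rmssd <- sqrt(mean(d^2))
  stats::setNames(
    c(60000 / m, m, md, mad_v, stats::sd(iv), stats::sd(d),
      stats::sd(iv) / m, if (md > 0) mad_v / md else NA_real_,
      rmssd, rmssd / m),
    nm)
}

# Welch power spectral density: Hann-windowed, linearly detrended segments
# with 50% overlap; windows shorter than one segment fall back to a single
# windowed periodogram.
welch_psd <- function(x, fs, seg_s = 120, overlap = 0.5) {
  n <- length(x)
  nseg <- min(n, round(seg_s * fs))
  step <- max(floor(nseg * (1 - overlap)), 1)
  w <- 0.5 - 0.5 * cos(2 * pi * seq(0, nseg - 1) / (nseg - 1))
  scale <- fs * sum(w^2)
  starts <- seq(1, n - nseg + 1, by = step)
  acc <- numeric(floor(nseg / 2) + 1)
  for (s in starts) {
    seg <- x[s:(s + nseg - 1)]
    tt <- seq_along(seg)
    seg <- stats::lm.fit(cbind(1, tt), seg)$residuals
    X <- stats::fft(seg * w)
    P <- Mod(X[seq_len(floor(nseg / 2) + 1)])^2 / scale
    P[c(-1, -length(P))] <- 2 * P[c(-1, -length(P))]
    acc <- acc + P
  }
  list(freq = (seq_len(floor(nseg / 2) + 1) - 1) * fs / nseg,
       psd = acc / length(starts))
}

band_power <- function(freq, psd, lo, hi) {
  df <- freq[2] - freq[1]
  sum(psd[freq >= lo & freq < hi]) * df
}

#' Frequency-domain statistics of an interval series
#'
#' The interval series is cubic-spline interpolated onto a uniform 4 Hz
#' grid, then a Welch power spectral density (Hann window, 120 s segments,
#' 50% overlap) is integrated over the low-frequency (0.04-0.15 Hz),
#' high-frequency (0.15-0.4 Hz) and very-high-frequency (0.4-0.5 Hz) bands.
#' Normalised powers divide by the total 0.04-0.5 Hz power. The very-low
#' band is never computed: it is not interpretable on short recordings.
#'
#' @param series An [interval_series()].
#' @param resample_fs Resampling rate (Hz).
#' @return Named numeric vector `lf`, `hf`, `lf_hf`, `vhf`, `lfn`, `hfn`,
#'   `lnhf` (power in ms^2); all `NA` when the window is shorter than 60 s
#'   or has fewer than 16 intervals.
#' @export
interval_spectral_stats <- function(series, resample_fs = 4) {
  nm <- c("lf", "hf", "lf_hf", "vhf", "lfn", "hfn", "lnhf")
  iv <- series$intervals
  tt <- series$event_times[-1]
  if (length(iv) < 16 || (max(tt) - min(tt)) < 60)
    return(stats::setNames(rep(NA_real_, length(nm)), nm))
  grid <- seq(min(tt), max(tt), by = 1 / resample_fs)
  xi <- stats::spline(tt, iv, xout = grid)$y
  ps <- welch_psd(xi, resample_fs)
  lf <- band_power(ps$freq, ps$psd, 0.04, 0.15)
  hf <- band_power(ps$freq, ps$psd, 0.15, 0.40)
  vhf <- band_power(ps$freq, ps$psd, 0.40, 0.50)
  tot <- lf + hf + vhf
  stats::setNames(
    c(lf, hf, if (hf > 0) lf / hf else NA_real_, vhf,
      if (tot > 0) lf / tot else NA_real_,
      if (tot > 0) hf / tot else NA_real_,
      if (hf > 0) log(hf) else NA_real_),
    nm)
}

#' Poincare-plot statistics of an interval series
#'
#' SD1 (spread perpendicular to the identity line) is RMSSD/sqrt(2); SD2
#' (spread along the identity line) is sqrt(2 var - SD1^2). With the
#' conventional ellipse axes T = 4 SD1 and L = 4 SD2: the cardiac
#' sympathetic index CSI = L/T, the cardiac vagal index CVI = log10(L T),
#' and the modified CSI = L^2/T.
#'
#' @param series An [interval_series()].
#' @return Named numeric vector `sd1`, `sd2`, `sd2_sd1`, `csi`, `cvi`,
#'   `csi_mod`; ratios are `NA` for zero-variance series.
#' @export
poincare_stats <- function(series) {
  nm <- c("sd1", "sd2", "sd2_sd1", "csi", "cvi", "csi_mod")
  iv <- series$intervals
  if (length(iv) < 3)
    return(stats::setNames(rep(NA_real_, length(nm)), nm))
  sd1 <- sqrt(mean(diff(iv)^2) / 2)
  sd2 <- sqrt(max(2 * stats::var(iv) - sd1^2, 0))
  ratio <- if (sd1 > 0) sd2 / sd1 else NA_real_
  cvi <- if (sd1 > 0 && sd2 > 0) log10(16 * sd1 * sd2) else NA_real_
  csi_mod <- if (sd1 > 0) 4 * sd2^2 / sd1 else NA_real_
  stats::setNames(c(sd1, sd2, ratio, ratio, cvi, csi_mod), nm)
}

#' Histogram-based and pNNx statistics of an inter-beat interval series
#'
#' pNN50 and pNN20 are the proportions of successive-difference magnitudes
#' strictly greater than 50 and 20 ms. The interval histogram uses a
#' 1/128 s bin width; HTI is the number of intervals divided by the modal
#' bin count, and TINN is the base width (ms) of the least-squares
#' triangular fit to the histogram with apex fixed at the mode.
#'
#' @param series An [interval_series()] of kind `"IBI"`.
#' @return Named numeric vector `pnn50`, `pnn20`, `tinn`, `hti`; histogram
#'   metrics are `NA` with fewer than 10 intervals.
#' @export
ecg_extra_stats <- function(series) {
  nm <- c("pnn50", "pnn20", "tinn", "hti")
  iv <- series$intervals
  out <- stats::setNames(rep(NA_real_, 4), nm)
  if (length(iv) >= 3) {
    d <- abs(diff(iv))
    # strict inequality; the epsilon guards float noise from time arithmetic
    out["pnn50"] <- mean(d > 50 + 1e-9)
    out["pnn20"] <- mean(d > 20 + 1e-9)
  }
  if (length(iv) < 10) return(out)

  bw <- 1000 / 128                                # ms
  lo <- floor(min(iv) / bw) * bw
  hi <- ceiling(max(iv) / bw) * bw
  if (hi <= lo) hi <- lo + bw
  breaks <- seq(lo, hi, by = bw)
  cnt <- graphics::hist(iv, breaks = breaks, plot = FALSE)$counts
  centers <- breaks[-length(breaks)] + bw / 2
  peak <- which.max(cnt)
  out["hti"] <- length(iv) / max(cnt)
  if (length(cnt) == 1) { out["tinn"] <- 0; return(out) }

  # least-squares triangle: apex at the modal bin, feet N < apex < M
  best <- Inf; best_nm <- c(centers[peak], centers[peak])
  cand_n <- c(centers[seq_len(peak)] - bw, centers[peak] - bw / 2)
  cand_m <- c(centers[peak:length(cnt)] + bw, centers[peak] + bw / 2)
  y_pk <- cnt[peak]; x_pk <- centers[peak]
  for (N in cand_n) {
    if (N >= x_pk) next
    up <- pmax(pmin((centers - N) / (x_pk - N), 1), 0)
    for (M in cand_m) {
      if (M <= x_pk) next
      down <- pmax(pmin((M - centers) / (M - x_pk), 1), 0)
      q <- y_pk * pmin(up, down)
      sse <- sum((cnt - q)^2)
      if (sse < best - 1e-12) { best <- sse; best_nm <- c(N, M) }
    }
  }
  out["tinn"] <- best_nm[2] - best_nm[1]
  out
}

#' Electrodermal indicators over a window
#'
#' Level statistics (mean, min, max, SD) of the filtered and tonic traces
#' within the window, the per-minute frequency of non-specific SCRs whose
#' peak falls in the window, and their mean amplitude (`NA` when no event
#' qualifies).
#'
#' @param components An `eda_components` object.
#' @param t0,t1 Window bounds in seconds (relative to the component trace).
#' @return Named numeric vector of the 10 electrodermal indicators.
#' @export
eda_stats <- function(components, t0, t1) {
  if (t1 - t0 < 10) stop("EDA indicator window must be >= 10 s", call. = FALSE)
  fs <- components$fs
  sl <- (floor(t0 * fs) + 1):min(ceiling(t1 * fs), length(components$filtered))
  if (length(sl) == 0) stop("empty EDA window", call. = FALSE)
  f <- components$filtered[sl]
  tn <- components$tonic[sl]
  ev <- components$scr_events
  ev <- ev[ev$peak_time >= t0 & ev$peak_time < t1, , drop = FALSE]
  mins <- (t1 - t0) / 60
  stats::setNames(
    c(mean(f), min(f), max(f), stats::sd(f),
      mean(tn), min(tn), max(tn), stats::sd(tn),
      if (nrow(ev)) mean(ev$amplitude) else NA_real_,
      nrow(ev) / mins),
    c("eda_mean", "eda_min", "eda_max", "eda_sd",
      "eda_tonic_mean", "eda_tonic_min", "eda_tonic_max", "eda_tonic_sd",
      "eda_scr_amp", "eda_scr_freq"))
}

# Approximate entropy with embedding dimension m and tolerance r
# (Chebyshev distance, self-matches included).
approx_entropy <- function(x, m = 2, r = 0.2 * stats::sd(x)) {
  if (length(x) < m + 2) return(NA_real_)
  if (!is.finite(r) || r <= 0) return(0)
  apen_cpp(as.numeric(x), as.integer(m), r)
}

# Detrended fluctuation analysis slope over box sizes `scales`.
dfa_exponent <- function(x, scales) {
  n <- length(x)
  y <- cumsum(x - mean(x))
  fl <- vapply(scales, function(s) {
    nb <- floor(n / s)
    if (nb < 2) return(NA_real_)
    res2 <- 0
    tt <- seq_len(s)
    for (b in seq_len(nb)) {
      seg <- y[((b - 1) * s + 1):(b * s)]
      fit <- stats::lm.fit(cbind(1, tt), seg)
      res2 <- res2 + sum(fit$residuals^2)
    }
    sqrt(res2 / (nb * s))
  }, numeric(1))
  ok <- is.finite(fl) & fl > 0
  if (sum(ok) < 3) return(NA_real_)
  stats::coef(stats::lm.fit(cbind(1, log(scales[ok])), log(fl[ok])))[2]
}

#' Respiration-specific indicators
#'
#' Mean respiratory amplitude (peak minus trough per cycle), approximate
#' entropy of the breath-to-breath series (m = 2, r = 0.2 SD, at least 100
#' intervals), and the long-term detrended-fluctuation exponent DFA2 (box
#' sizes 16-64), which is reported only when the series has more than 640
#' breath cycles and is therefore `NA` for within-session windows.
#'
#' @param cycles Breath-cycle list from [segment_breaths()] (already sliced
#'   to the window).
#' @param bb The matching [interval_series()] of kind `"BB"`.
#' @return Named numeric vector `amp_mean`, `apen`, `dfa2`.
#' @export
resp_extra_stats <- function(cycles, bb) {
  amp <- if (length(cycles$amplitudes) >= 3) mean(cycles$amplitudes)
         else NA_real_
  iv <- bb$intervals
  apen <- if (length(iv) >= 100) approx_entropy(iv) else NA_real_
  dfa2 <- if (length(iv) > 640)
    dfa_exponent(iv, unique(round(exp(seq(log(16), log(64), length.out = 8)))))
  else NA_real_
  c(amp_mean = amp, apen = apen, dfa2 = unname(dfa2))
}

# Porges-Bohrer style estimate: variance of the 0.12-0.40 Hz band of the
# uniformly resampled heart-period series, natural log of ms^2.
rsa_porges_bohrer <- function(ibi, resample_fs = 4) {
  iv <- ibi$intervals
  tt <- ibi$event_times[-1]
  if (length(iv) < 16 || (max(tt) - min(tt)) < 30) return(NA_real_)
  grid <- seq(min(tt), max(tt), by = 1 / resample_fs)
  xi <- stats::spline(tt, iv, xout = grid)$y
  bp <- signal::filtfilt(signal::butter(2, c(0.12, 0.40) / (resample_fs / 2),
                                        type = "pass"), xi - mean(xi))
  v <- stats::var(bp)
  if (v <= 0) NA_real_ else log(v)
}

#' Respiratory sinus arrhythmia indicators
#'
#' Peak-to-trough estimates: for each breath cycle, the longest heart period
#' during the cycle minus the shortest heart period during its inspiration.
#' A cycle is invalid (counted in `rsa_norsa`) when fewer than 2 heart
#' periods fall in the cycle or in its inspiration. Also reports the
#' band-limited variance estimate ([ln(ms^2)]) of the resampled heart-period
#' series over 0.12-0.40 Hz.
#'
#' @param ibi [interval_series()] of heart periods.
#' @param cycles Breath-cycle list (already sliced to the window).
#' @return Named numeric vector `rsa_mean`, `rsa_mean_log` (ln of the mean
#'   estimate), `rsa_sd`, `rsa_norsa`, `rsa_pb`.
#' @export
rsa_stats <- function(ibi, cycles) {
  nm <- c("rsa_mean", "rsa_mean_log", "rsa_sd", "rsa_norsa", "rsa_pb")
  n_cyc <- length(cycles$onsets)
  if (n_cyc < 3 || length(ibi$intervals) < 3)
    return(stats::setNames(c(rep(NA_real_, 3), n_cyc, NA_real_), nm))
  ends <- ibi$event_times[-1]                     # interval end times
  est <- rep(NA_real_, n_cyc)
  # locate each cycle's interval range once (ends are sorted)
  lo <- findInterval(cycles$onsets, ends, left.open = TRUE) + 1
  hi_insp <- findInterval(cycles$onsets + cycles$insp, ends,
                          left.open = TRUE)
  hi_cyc <- findInterval(cycles$onsets + cycles$insp + cycles$expir, ends,
                         left.open = TRUE)
  for (k in seq_len(n_cyc)) {
    if (hi_cyc[k] - lo[k] < 1 || hi_insp[k] - lo[k] < 1) next
    est[k] <- max(ibi$intervals[lo[k]:hi_cyc[k]]) -
      min(ibi$intervals[lo[k]:hi_insp[k]])
  }
  valid <- est[!is.na(est)]
  norsa <- sum(is.na(est))
  if (length(valid) == 0)
    return(stats::setNames(c(NA_real_, NA_real_, NA_real_, norsa, NA_real_), nm))
  m <- mean(valid)
  stats::setNames(
    c(m, if (m > 0) log(m) else NA_real_,
      if (length(valid) > 1) stats::sd(valid) else 0,
      norsa, rsa_porges_bohrer(ibi)),
    nm)
}

# Slice breath cycles to [t0, t1) by cycle onset.
slice_cycles <- function(cycles, t0, t1) {
  keep <- cycles$onsets >= t0 & cycles$onsets < t1
  list(onsets = cycles$onsets[keep], insp = cycles$insp[keep],
       expir = cycles$expir[keep], amplitudes = cycles$amplitudes[keep])
}

#' Compute the full 61-indicator vector for one window
#'
#' @param derived Derived series for one recording phase: a list with `ibi`
#'   (heart-period [interval_series()]), `bb` (breath-to-breath series),
#'   `cycles` (breath cycles) and `eda` (an `eda_components`), all on the
#'   phase-relative time axis.
#' @param t0,t1 Window bounds (s) within the phase.
#' @return Named numeric vector of length 61, ordered as
#'   [indicator_catalog()]. Indicators undefined on the window are `NA`.
#' @export
compute_indicators <- function(derived, t0, t1) {
  ibi <- slice_intervals(derived$ibi, t0, t1)
  bb <- slice_intervals(derived$bb, t0, t1)
  cyc <- slice_cycles(derived$cycles, t0, t1)

  hrv_t <- interval_time_stats(ibi)
  hrv_f <- interval_spectral_stats(ibi)
  hrv_p <- poincare_stats(ibi)
  hrv_e <- ecg_extra_stats(ibi)
  rrv_t <- interval_time_stats(bb)
  rrv_f <- interval_spectral_stats(bb)
  rrv_p <- poincare_stats(bb)

  out <- c(
    eda_stats(derived$eda, t0, t1),
    stats::setNames(
      c(hrv_t, hrv_f[c("lf", "hf", "lf_hf")], hrv_p[c("sd1", "sd2", "sd2_sd1")],
        hrv_e[c("pnn50", "pnn20", "tinn", "hti")],
        hrv_f[c("vhf", "lfn", "hfn", "lnhf")],
        hrv_p[c("csi", "cvi", "csi_mod")]),
      paste0("hrv_", c(names(hrv_t), "lf", "hf", "lf_hf",
                       "sd1", "sd2", "sd2_sd1", "pnn50", "pnn20", "tinn",
                       "hti", "vhf", "lfn", "hfn", "lnhf",
                       "csi", "cvi", "csi_mod"))),
    stats::setNames(
      c(rrv_t, rrv_f[c("lf", "hf", "lf_hf")], rrv_p[c("sd1", "sd2", "sd2_sd1")]),
      paste0("rrv_", c(names(rrv_t), "lf", "hf", "lf_hf",
                       "sd1", "sd2", "sd2_sd1"))),
    stats::setNames(resp_extra_stats(cyc, bb),
                    c("rrv_amp_mean", "rrv_apen", "rrv_dfa2")),
    rsa_stats(ibi, cyc))
  stopifnot(identical(names(out), indicator_catalog()$name))
  out
}
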