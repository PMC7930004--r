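#' Construct an event-interval series
#'
#' Container for inter-beat (IBI) or breath-to-breath (BB) interval series:
#' event times in seconds and successive intervals in milliseconds.
#' Intervals outside the physiological range (IBI 300-2000 ms, BB
#' 1500-15000 ms) are flagged, not dropped.
#'
#' @param event_times Strictly increasing event times (s).
#' @param kind `"IBI"` or `"BB"`.
#' @return An object of class `interval_series` with fields `event_times`,
#'   `intervals` (ms), `kind`, `flagged` (logical per interval).
#' @export
interval_series <- function(event_times, kind = c("IBI", "BB")) {
  kind <- match.arg(kind)
  if (length(event_times) > 1 && any(diff(event_times) <= 0))
    stop("event times must be strictly increasing", call. = FALSE)
  iv <- diff(event_times) * 1000
  rng <- if (kind == "IBI") c(300, 2000) else c(1500, 15000)
  obj <- list(event_times = event_times, intervals = iv, kind = kind,
              flagged = iv < rng[1] | iv > rng[2])
  class(obj) <- "interval_series"
  obj
}

# Slice an interval series to a window [t0, t1): keep intervals whose both
# endpoints fall inside the window.
slice_intervals <- function(series, t0, t1) {
  tt <- series$event_times
  keep <- tt >= t0 & tt < t1
  interval_series(tt[keep], series$kind)
}

#' Detect R-peaks in a filtered ECG
#'
#' QRS detection in the style of envelope-based detectors: rectified
#' derivative of the band-passed signal, 80 ms moving-window integration,
#' block-adaptive thresholding, a 250 ms refractory period, and final R-wave
#' localisation at the absolute maximum of the filtered signal near each
#' envelope peak.
#'
#' @param x Band-pass filtered ECG (see [filter_ecg()]).
#' @param fs Sampling rate (Hz).
#' @return An [interval_series()] of kind `"IBI"`.
#' @export
detect_r_peaks <- function(x, fs) {
  if (length(x) < 10 * fs)
    stop("need at least 10 s of ECG", call. = FALSE)
  env <- moving_average(abs(c(0, diff(x))), max(round(0.08 * fs), 3))

  # block-adaptive threshold: half of a high quantile per 10 s block
  blk <- max(round(10 * fs), 1)
  nb <- ceiling(length(env) / blk)
  thr <- numeric(length(env))
  for (b in seq_len(nb)) {
    sl <- ((b - 1) * blk + 1):min(b * blk, length(env))
    # decimated quantile: ample resolution for a threshold level
    sub <- env[sl[seq(1, length(sl), by = 10)]]
    thr[sl] <- 0.4 * stats::quantile(sub, 0.95, names = FALSE)
  }
  if (max(env) <= 0 || stats::sd(x) < 1e-12)
    stop("no detectable R-peaks (flat signal)", call. = FALSE)

  above <- env > thr & env > 0.05 * max(env)
  # candidate local maxima of the envelope
  cand <- which(above &
                  env >= c(-Inf, env[-length(env)]) &
                  env > c(env[-1], -Inf))
  if (length(cand) == 0)
    stop("no detectable R-peaks", call. = FALSE)

  # refractory: greedy merge of candidates closer than 250 ms (keep larger)
  refr <- round(0.25 * fs)
  keep <- logical(length(cand))
  last <- -Inf; last_i <- 0
  for (i in seq_along(cand)) {
    if (cand[i] - last >= refr) {
      keep[i] <- TRUE; last <- cand[i]; last_i <- i
    } else if (env[cand[i]] > env[cand[last_i]]) {
      keep[last_i] <- FALSE; keep[i] <- TRUE; last <- cand[i]; last_i <- i
    }
  }
  cand <- cand[keep]

  # refine to the R wave: maximum |x| within +/- 50 ms
  half <- round(0.05 * fs)
  peaks <- vapply(cand, function(i) {
    sl <- max(i - half, 1):min(i + half, length(x))
    sl[which.max(abs(x[sl]))]
  }, integer(1))
  peaks <- sort(unique(peaks))
  if (length(peaks) < 2)
    stop("no detectable R-peaks", call. = FALSE)
  interval_series((peaks - 1) / fs, "IBI")
}

#' Segment a filtered respiration signal into breath cycles
#'
#' Cycle onsets are placed at troughs (inspiration starts); each cycle is an
#' inspiration (trough to peak) followed by an expiration (peak to next
#' trough); per-cycle amplitude is peak minus trough. Extrema are found
#' between zero crossings of the mean-removed signal, and cycles shorter
#' than 1.5 s or with amplitude below 10% of the median are merged away.
#'
#' @param x Band-passed (and optionally smoothed) respiration signal.
#' @param fs Sampling rate (Hz).
#' @return List with `cycles` (list: `onsets`, `insp`, `expir`, `amplitudes`)
#'   and `bb` (an [interval_series()] of kind `"BB"`).
#' @export
segment_breaths <- function(x, fs) {
  xz <- x - mean(x)
  if (stats::sd(xz) < 1e-12)
    stop("no respiratory cycles detected (flat signal)", call. = FALSE)
  s <- sign(xz)
  s[s == 0] <- 1
  cross <- which(diff(s) != 0)                      # index before crossing
  if (length(cross) < 6)
    stop("need at least 3 full respiratory cycles", call. = FALSE)

  up <- cross[xz[cross] < 0]                        # upward crossings
  down <- cross[xz[cross] > 0]                      # downward crossings

  # troughs: minimum between a downward and the next upward crossing; a
  # final descending stretch counts when its minimum is interior, and a
  # recording that opens rising from its minimum starts on a cycle onset
  troughs <- integer(0); peaks <- integer(0)
  if (length(up) && (length(down) == 0 || up[1] < down[1])) {
    cand <- which.min(xz[1:up[1]])
    # only a genuinely deep opening minimum counts as an onset
    if (xz[cand] < -0.5 * stats::sd(xz)) troughs <- cand
  }
  for (d in down) {
    u <- up[up > d]
    sl <- if (length(u)) d:u[1] else d:length(xz)
    cand <- sl[which.min(xz[sl])]
    if (length(u) == 0 && cand >= length(xz) - 1) break
    troughs <- c(troughs, cand)
  }
  for (u in up) {
    d <- down[down > u]
    if (length(d) == 0) break
    sl <- u:d[1]
    peaks <- c(peaks, sl[which.max(xz[sl])])
  }
  if (length(troughs) < 3)
    stop("need at least 3 full respiratory cycles", call. = FALSE)

  # enforce minimum cycle duration (1.5 s) by dropping the shallower trough
  min_cyc <- round(1.5 * fs)
  i <- 2
  while (i <= length(troughs)) {
    if (troughs[i] - troughs[i - 1] < min_cyc) {
      drop <- if (xz[troughs[i]] < xz[troughs[i - 1]]) i - 1 else i
      troughs <- troughs[-drop]
    } else i <- i + 1
  }
  if (length(troughs) < 3)
    stop("need at least 3 full respiratory cycles", call. = FALSE)

  onsets <- (troughs - 1) / fs
  n_cyc <- length(troughs) - 1
  insp <- numeric(n_cyc); amp <- numeric(n_cyc); expd <- numeric(n_cyc)
  ok <- logical(n_cyc)
  for (k in seq_len(n_cyc)) {
    pk <- peaks[peaks > troughs[k] & peaks < troughs[k + 1]]
    if (length(pk) == 0) { ok[k] <- FALSE; next }
    pk <- pk[which.max(xz[pk])]
    insp[k] <- (pk - troughs[k]) / fs
    expd[k] <- (troughs[k + 1] - pk) / fs
    amp[k] <- xz[pk] - min(xz[troughs[k]], xz[troughs[k + 1]])
    ok[k] <- TRUE
  }
  # drop degenerate cycles with no interior peak or negligible amplitude
  med_amp <- stats::median(amp[ok])
  ok <- ok & amp > 0.1 * med_amp
  keep_on <- c(ok, TRUE)          # keep final trough as the last boundary
  cycles <- list(onsets = onsets[-length(onsets)][ok],
                 insp = insp[ok], expir = expd[ok], amplitudes = amp[ok])
  list(cycles = cycles,
       bb = interval_series(onsets[keep_on], "BB"))
}
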