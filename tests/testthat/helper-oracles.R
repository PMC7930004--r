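# Brute-force oracle implementations, coded independently of the package
# internals (explicit sums and loops), used to validate the indicator
# catalog on random series.

oracle_time_stats <- function(iv) {
  n <- length(iv)
  m <- sum(iv) / n
  srt <- sort(iv)
  med <- if (n %% 2 == 1) srt[(n + 1) / 2] else (srt[n / 2] + srt[n / 2 + 1]) / 2
  mad_v <- sum(abs(iv - med)) / n
  sdv <- sqrt(sum((iv - m)^2) / (n - 1))
  d <- iv[-1] - iv[-n]
  md <- sum(d) / length(d)
  sdsd <- sqrt(sum((d - md)^2) / (length(d) - 1))
  rmssd <- sqrt(sum(d^2) / length(d))
  c(mean_rate = 60000 / m, mean = m, median = med, mad = mad_v, sd = sdv,
    sdsd = sdsd, cv = sdv / m, mcv = mad_v / med, rmssd = rmssd,
    cvsd = rmssd / m)
}

oracle_poincare <- function(iv) {
  n <- length(iv)
  d <- iv[-1] - iv[-n]
  rmssd <- sqrt(sum(d^2) / length(d))
  sd1 <- rmssd / sqrt(2)
  m <- sum(iv) / n
  v <- sum((iv - m)^2) / (n - 1)
  sd2 <- sqrt(max(2 * v - sd1^2, 0))
  csi <- (4 * sd2) / (4 * sd1)
  c(sd1 = sd1, sd2 = sd2, sd2_sd1 = sd2 / sd1, csi = csi,
    cvi = log10(4 * sd2 * 4 * sd1), csi_mod = (4 * sd2)^2 / (4 * sd1))
}

oracle_pnn <- function(iv, x) {
  d <- abs(iv[-1] - iv[-length(iv)])
  sum(d > x) / length(d)
}

# Reference band power: the same Welch definition (Hann window, linear
# detrend, 120 s segments, 50% overlap) recomputed with explicit
# discrete-Fourier sums.
oracle_band_powers <- function(series, bands, resample_fs = 4) {
  iv <- series$intervals
  tt <- series$event_times[-1]
  grid <- seq(min(tt), max(tt), by = 1 / resample_fs)
  x <- stats::spline(tt, iv, xout = grid)$y
  n <- length(x)
  nseg <- min(n, 120 * resample_fs)
  step <- max(floor(nseg / 2), 1)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(nseg - 1)) / (nseg - 1))
  starts <- seq(1, n - nseg + 1, by = step)
  nf <- floor(nseg / 2) + 1
  freq <- (0:(nf - 1)) * resample_fs / nseg
  psd_acc <- numeric(nf)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nseg - 1)]
    tt2 <- seq_len(nseg)
    fit <- stats::lm(seg ~ tt2)
    seg <- seg - stats::fitted(fit)
    sw <- seg * w
    for (k in seq_len(nf)) {
      re <- sum(sw * cos(-2 * pi * (k - 1) * (0:(nseg - 1)) / nseg))
      im <- sum(sw * sin(-2 * pi * (k - 1) * (0:(nseg - 1)) / nseg))
      p <- (re^2 + im^2) / (resample_fs * sum(w^2))
      if (k > 1 && k < nf) p <- 2 * p
      psd_acc[k] <- psd_acc[k] + p
    }
  }
  psd <- psd_acc / length(starts)
  df <- freq[2] - freq[1]
  vapply(bands, function(b) sum(psd[freq >= b[1] & freq < b[2]]) * df,
         numeric(1))
}

# Random plausible interval series (ms) as an interval_series object.
random_ibi_series <- function(n, mean_ms = 800, sd_ms = 50) {
  iv <- pmax(stats::rnorm(n, mean_ms, sd_ms), 300)
  interval_series(cumsum(c(0.5, iv / 1000)), "IBI")
}

# Event times whose interval series follows a sinusoidal modulation at
# `f_mod` Hz around `base_ms`.
modulated_ibi_series <- function(duration_s, base_ms = 1000, amp_ms = 50,
                                 f_mod = 0.25) {
  tt <- 0.5
  times <- tt
  while (tt < duration_s) {
    ibi <- base_ms + amp_ms * sin(2 * pi * f_mod * tt)
    tt <- tt + ibi / 1000
    times <- c(times, tt)
  }
  interval_series(times, "IBI")
}
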