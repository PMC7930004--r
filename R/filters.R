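#' @useDynLib physiowork, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Full linear convolution conv(x, h) via overlap-save FFT blocks.
conv_fft <- function(x, h) {
  n <- length(x); nh <- length(h)
  nout <- n + nh - 1
  block <- max(2^ceiling(log2(4 * nh)), 2^15)
  if (block >= nout) {
    nfft <- stats::nextn(nout, c(2, 3, 5))
    y <- Re(stats::fft(stats::fft(c(x, numeric(nfft - n))) *
                       stats::fft(c(h, numeric(nfft - nh))), inverse = TRUE)) / nfft
    return(y[seq_len(nout)])
  }
  H <- stats::fft(c(h, numeric(block - nh)))
  step <- block - nh + 1
  # xq = (nh-1) leading zeros, signal, tail zeros so every block is complete
  xq <- c(numeric(nh - 1), x, numeric(nh - 1 + block))
  y <- numeric(nout + step)
  pos <- 1
  while (pos <= nout) {
    blk <- xq[pos:(pos + block - 1)]
    yy <- Re(stats::fft(stats::fft(blk) * H, inverse = TRUE)) / block
    y[pos:(pos + step - 1)] <- yy[nh:block]
    pos <- pos + step
  }
  y[seq_len(nout)]
}

# Zero-phase FIR filtering: linear-phase odd-length kernel, group delay
# (length(h)-1)/2 compensated, reflected edges.
fir_filtfft <- function(x, h) {
  nh <- length(h)
  if (nh %% 2 == 0) stop("FIR kernel must have odd length")
  half <- (nh - 1) / 2
  n <- length(x)
  pad <- min(half, n - 1)
  xe <- c(rev(x[seq_len(pad) + 1]), x, rev(x[n - seq_len(pad)]))
  y <- conv_fft(xe, h)
  y[(pad + half) + seq_len(n)]
}

# Windowed-sinc FIR length for a given transition width (Hamming window rule).
fir_length <- function(fs, transition) {
  n <- ceiling(3.3 * fs / transition)
  if (n %% 2 == 1) n <- n + 1
  n
}

#' Band-pass filter an ECG signal (3-45 Hz, zero phase)
#'
#' Windowed-sinc linear-phase FIR band-pass with 3 and 45 Hz cut-offs,
#' applied with delay compensation so the output has the same length and
#' alignment as the input. The kernel length follows from a 2 Hz transition
#' width, which gives > 20 dB attenuation one octave below the low cut-off.
#'
#' @param x Numeric ECG signal (mV).
#' @param fs Sampling rate (Hz); must exceed 90 Hz so the 45 Hz edge exists.
#' @return Filtered signal, same length as `x`.
#' @export
filter_ecg <- function(x, fs) {
  if (fs <= 90) stop("sampling rate too low for a 3-45 Hz band", call. = FALSE)
  h <- signal::fir1(fir_length(fs, 2), c(3, 45) / (fs / 2), type = "pass")
  fir_filtfft(x, h)
}

# Decimate by integer factor using block means (box anti-alias filter);
# adequate for signals whose content is far below the new Nyquist rate.
decimate_mean <- function(x, factor) {
  n <- floor(length(x) / factor) * factor
  colMeans(matrix(x[seq_len(n)], nrow = factor))
}

#' Centred moving-average smoothing
#'
#' @param x Numeric vector.
#' @param w Window length in samples (odd lengths keep exact centring; even
#'   lengths are shifted by half a sample as usual for box smoothing).
#' @return Smoothed vector, same length (edges use shrinking windows).
#' @export
moving_average <- function(x, w) {
  if (w <= 1) return(x)
  n <- length(x)
  cs <- cumsum(c(0, x))
  half_lo <- floor((w - 1) / 2)
  half_hi <- w - 1 - half_lo
  lo <- pmax(seq_len(n) - half_lo, 1)
  hi <- pmin(seq_len(n) + half_hi, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Preprocess an electrodermal activity signal
#'
#' Downsamples to 50 Hz (block means), applies a windowed-sinc FIR low-pass
#' at 5 Hz, then box-smooths with a window of three quarters of the output
#' sampling rate (0.75 x 50 = 37.5, rounded to 37 samples).
#'
#' @param x Raw EDA (uS).
#' @param fs Input sampling rate (>= 50 Hz).
#' @return Filtered signal at 50 Hz with attribute `fs = 50`.
#' @export
preprocess_eda <- function(x, fs) {
  if (fs < 50) stop("EDA sampling rate must be >= 50 Hz", call. = FALSE)
  fs_out <- 50
  if (fs > fs_out) {
    if (fs %% fs_out != 0)
      stop("sampling rate must be a multiple of 50 Hz", call. = FALSE)
    x <- decimate_mean(x, fs %/% fs_out)
  }
  h <- signal::fir1(fir_length(fs_out, 2), 5 / (fs_out / 2), type = "low")
  y <- fir_filtfft(x, h)
  y <- moving_average(y, 37)
  attr(y, "fs") <- fs_out
  y
}

# Zero-phase Butterworth band-pass via the frequency-domain squared-magnitude
# response (the forward-backward equivalent), numerically stable at very low
# normalised cut-offs where transfer-function filtering degenerates.
butter_bandpass_zerophase <- function(x, fs, f_lo, f_hi, order = 2) {
  n <- length(x)
  nfft <- stats::nextn(2 * n, c(2, 3, 5))
  xe <- c(x, rev(x), numeric(nfft - 2 * n))       # even extension
  f <- c(seq(0, nfft / 2), seq(-nfft / 2 + 1, -1)) * fs / nfft
  f <- abs(f[seq_len(nfft)])
  xi <- ifelse(f == 0, Inf, (f^2 - f_lo * f_hi) / (f * (f_hi - f_lo)))
  H2 <- 1 / (1 + xi^(2 * order))                  # |H|^2: zero-phase pass
  y <- Re(stats::fft(stats::fft(xe) * H2, inverse = TRUE)) / nfft
  y[seq_len(n)]
}

#' Preprocess a respiration signal
#'
#' Second-order Butterworth band-pass between 0.1 and 0.35 Hz applied with
#' zero phase, optionally followed by rectangular (box) smoothing over a 3 s
#' window. Output has the same length as the input.
#'
#' @param x Raw respiration signal.
#' @param fs Sampling rate (Hz).
#' @param smooth Apply the 3 s rectangular smoothing window (default TRUE).
#'   The smoothing attenuates even in-band components appreciably (a 3 s box
#'   passes a 0.25 Hz sine at ~0.3 amplitude), so amplitude-calibration tests
#'   may disable it.
#' @return Filtered signal, same length as `x`.
#' @export
preprocess_resp <- function(x, fs, smooth = TRUE) {
  if (length(x) / fs < 30)
    stop("respiration recording too short (< 30 s)", call. = FALSE)
  y <- butter_bandpass_zerophase(x, fs, 0.1, 0.35, order = 2)
  if (smooth) y <- moving_average(y, max(round(3 * fs), 1))
  y
}
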