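# Package-level cache for decomposition design objects keyed by signal
# length; rebuilding the spline basis for every subject would dominate
# runtime in cohort processing.
.pw_cache <- new.env(parent = emptyenv())

# Cubic B-spline tonic basis with knots every `knot_s` seconds, plus the
# ridge-regularised normal-equation factor for the tonic update.
tonic_basis <- function(n, fs, knot_s = 10, gamma = 1e-2) {
  key <- sprintf("B_%d_%g_%g", n, fs, knot_s)
  if (!is.null(.pw_cache[[key]])) return(.pw_cache[[key]])
  tt <- (seq_len(n) - 1) / fs
  dur <- tt[n]
  inner <- seq(0, dur, by = knot_s)
  if (max(inner) < dur) inner <- c(inner, dur)
  knots <- c(rep(0, 3), inner, rep(dur, 3))   # boundary multiplicity 4
  Bd <- splines::splineDesign(knots, tt, ord = 4, outer.ok = TRUE)
  B <- methods::as(Matrix::Matrix(Bd, sparse = TRUE), "CsparseMatrix")
  BtB <- Matrix::crossprod(B)
  fac <- Matrix::Cholesky(BtB + gamma * Matrix::Diagonal(ncol(B)))
  out <- list(B = B, fac = fac)
  .pw_cache[[key]] <- out
  out
}

#' Decompose a filtered EDA signal into tonic, phasic and noise terms
#'
#' Models the filtered skin-conductance signal as the sum of a smooth tonic
#' component (cubic B-spline with 10 s knots, light ridge penalty), a phasic
#' component driven by a sparse non-negative sudomotor driver convolved with
#' a bi-exponential Bateman kernel (0.7 s rise, 2 s decay time constants),
#' and a residual noise term. The convex program
#' \deqn{\min_{q \ge 0, l}\; \tfrac12\|y - Hq - Bl\|^2 + \alpha 1^T q +
#'   \tfrac{\gamma}{2}\|l\|^2}
#' is solved by block coordinate descent: exact non-negative soft-threshold
#' updates of the driver weights alternate with the closed-form ridge
#' solution for the tonic spline coefficients.
#'
#' @param x Filtered EDA at `fs` Hz (see [preprocess_eda()]); at least 30 s.
#' @param fs Sampling rate (Hz), 50 by default.
#' @param alpha L1 weight on the driver (uS x samples). The default soft
#'   thresholds driver pulses below ~0.01 uS, well under the SCR amplitude
#'   criterion.
#' @param gamma Ridge weight on the tonic spline coefficients.
#' @param driver_spacing_s Driver knot spacing in seconds (grid of candidate
#'   SCR onsets).
#' @param max_iter Maximum outer iterations (each = 3 driver sweeps + 1
#'   tonic update).
#' @param tol Convergence tolerance on the largest driver update (uS).
#' @param scr_amp_min Amplitude criterion forwarded to [detect_scrs()].
#' @return An object of class `eda_components`: `filtered`, `tonic`,
#'   `phasic`, `noise` (all same length), `driver` (knot times and weights),
#'   `fs`, `scr_events` (data frame from [detect_scrs()]), and solver
#'   diagnostics `iterations`, `converged`.
#' @export
decompose_eda <- function(x, fs = 50, alpha = 0.5, gamma = 1e-2,
                          driver_spacing_s = 0.5, max_iter = 150,
                          tol = 5e-4, scr_amp_min = 0.05) {
  x <- as.numeric(x)
  n <- length(x)
  if (n / fs < 30)
    stop("need at least 30 s of EDA for decomposition", call. = FALSE)

  h <- bateman_kernel(fs, tau_rise = 0.7, tau_decay = 2, t_max = 10)
  spacing <- max(round(driver_spacing_s * fs), 1)
  idx <- seq(0L, n - 2L, by = spacing)            # 0-based knot starts
  hh <- vapply(idx, function(s0) {
    len <- min(length(h), n - s0)
    sum(h[seq_len(len)]^2)
  }, numeric(1))

  tb <- tonic_basis(n, fs, gamma = gamma)
  q <- numeric(length(idx))
  # the ridge shrinks spline coefficients toward zero, so fit the tonic on
  # the mean-centred signal to avoid boundary droop toward 0 uS
  mu <- mean(x)
  l <- Matrix::solve(tb$fac, Matrix::crossprod(tb$B, x - mu))
  tonic <- mu + as.numeric(tb$B %*% l)
  r <- x - tonic

  converged <- FALSE
  it <- 0
  omega <- 1.9    # over-relaxation on the tonic block; the tonic and the
                  # driver share a low-frequency subspace and plain
                  # alternation crawls along it
  for (it in seq_len(max_iter)) {
    md <- cd_driver_pass(r, q, h, as.integer(idx), hh, alpha, 8L, tol)
    # tonic refit on signal minus phasic
    y_minus_ph <- r + tonic
    l <- Matrix::solve(tb$fac, Matrix::crossprod(tb$B, y_minus_ph - mu))
    tonic_ls <- mu + as.numeric(tb$B %*% l)
    dt <- max(abs(tonic_ls - tonic))
    tonic_new <- tonic + omega * (tonic_ls - tonic)
    r <- r + tonic - tonic_new
    tonic <- tonic_new
    if (md < tol && dt < tol) { converged <- TRUE; break }
  }
  if (!converged && max(abs(r)) > 10 * stats::sd(x) + 1e-6)
    stop("EDA decomposition did not converge (max driver update ",
         signif(tol, 3), " not reached)", call. = FALSE)

  phasic <- driver_convolve(q, h, as.integer(idx), n)
  noise <- x - tonic - phasic
  comp <- list(filtered = x, tonic = tonic, phasic = phasic, noise = noise,
               driver = list(times = idx / fs, weights = q),
               fs = fs, iterations = it, converged = converged)
  class(comp) <- "eda_components"
  comp$scr_events <- detect_scrs(comp, amp_min = scr_amp_min)
  comp
}

#' Detect non-specific skin-conductance responses from a decomposition
#'
#' Scans the phasic component for trough-to-peak deflections with amplitude
#' (peak level minus onset level) at or above `amp_min`. For each event the
#' onset time, peak time, amplitude, rise time and half-recovery time (time
#' from peak until the phasic level falls below peak minus half the
#' amplitude; `NA` when the next response starts first) are reported.
#'
#' @param components An `eda_components` object (see [decompose_eda()]).
#' @param amp_min Minimum amplitude in uS (default 0.05).
#' @return Data frame with columns `onset`, `peak_time`, `amplitude`,
#'   `rise_time`, `half_recovery`; zero rows when no event qualifies.
#' @export
detect_scrs <- function(components, amp_min = 0.05) {
  p <- components$phasic
  fs <- components$fs
  empty <- data.frame(onset = numeric(0), peak_time = numeric(0),
                      amplitude = numeric(0), rise_time = numeric(0),
                      half_recovery = numeric(0))
  if (max(p) - min(p) < amp_min) return(empty)

  # alternating extrema of the phasic trace, then prominence merging:
  # adjacent trough/peak pairs whose swing is below half the amplitude
  # criterion are staircase wiggles of the sparse driver, not responses
  dp <- diff(p)
  s <- sign(dp); s[s == 0] <- 1
  turns <- which(diff(s) != 0) + 1
  ext <- unique(as.integer(c(1L, turns, length(p))))
  thr <- amp_min / 2
  repeat {
    sw <- abs(diff(p[ext]))
    if (length(sw) == 0) break
    j <- which.min(sw)
    if (sw[j] >= thr) break
    if (j == 1) ext <- ext[-2]
    else if (j == length(sw)) ext <- ext[-(length(ext) - 1)]
    else ext <- ext[-c(j, j + 1)]
  }
  if (length(ext) < 3) return(empty)

  out <- empty
  for (i in 2:(length(ext) - 1)) {
    pk <- ext[i]
    if (p[pk] <= p[ext[i - 1]] || p[pk] <= p[ext[i + 1]]) next  # not a peak
    tr <- ext[i - 1]
    amp <- p[pk] - p[tr]
    if (amp < amp_min) next
    # refine the onset: last sample before the peak still within 5% of the
    # trough level (a flat pre-response plateau should not count as rise)
    seg <- tr:pk
    low <- which(p[seg] <= p[tr] + 0.05 * amp)
    if (length(low)) tr <- seg[max(low)]
    amp <- p[pk] - p[tr]
    # half recovery: first sample after the peak at or below peak - amp/2;
    # missing when the next response rises before that level is reached
    target <- p[pk] - amp / 2
    nxt_tr <- ext[i + 1]
    seg_after <- p[(pk + 1):nxt_tr]
    hit <- which(seg_after <= target)
    half_rec <- if (length(hit)) hit[1] / fs else NA_real_
    out <- rbind(out, data.frame(
      onset = (tr - 1) / fs, peak_time = (pk - 1) / fs, amplitude = amp,
      rise_time = (pk - tr) / fs, half_recovery = half_rec))
  }
  out
}
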