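test_that("the catalog counts 61 indicators: 10 + 27 + 19 + 5", {
  cat <- indicator_catalog()
  expect_equal(nrow(cat), 61)
  expect_equal(as.integer(table(cat$signal)[c("EDA", "ECG", "RESP", "RSA")]),
               c(10L, 27L, 19L, 5L))
  expect_false(anyDuplicated(cat$name) > 0)
})

test_that("time-domain statistics match hand-computed values", {
  s <- interval_series(cumsum(c(1, 0.800, 0.810, 0.790, 0.805)), "IBI")
  st <- interval_time_stats(s)
  expect_equal(unname(st["rmssd"]), sqrt((10^2 + 20^2 + 15^2) / 3),
               tolerance = 1e-9)
  expect_equal(unname(st["sdsd"]), stats::sd(c(10, -20, 15)), tolerance = 1e-9)
  expect_equal(unname(st["sd"]), stats::sd(c(800, 810, 790, 805)),
               tolerance = 1e-9)

  cst <- interval_time_stats(interval_series(seq(0, 10, by = 1), "IBI"))
  expect_equal(unname(cst["mean_rate"]), 60)
  expect_equal(unname(cst["rmssd"]), 0)
  expect_equal(unname(cst["sd"]), 0)
  expect_equal(unname(cst["cv"]), 0)

  expect_true(all(is.na(interval_time_stats(
    interval_series(c(0, 0.8, 1.6), "IBI")))))
})

test_that("Poincare geometry follows the RMSSD-based estimator", {
  s <- interval_series(cumsum(c(1, 0.800, 0.810, 0.790, 0.805)), "IBI")
  p <- poincare_stats(s)
  rmssd <- sqrt((10^2 + 20^2 + 15^2) / 3)
  expect_equal(unname(p["sd1"]), rmssd / sqrt(2), tolerance = 1e-9)
  expect_equal(unname(p["csi"]), unname(p["sd2_sd1"]))

  # strong alternation: short-term spread dominates
  alt <- interval_series(cumsum(c(1, rep(c(0.9, 1.1), 10))), "IBI")
  pa <- poincare_stats(alt)
  expect_gt(unname(pa["sd1"]), unname(pa["sd2"]))
})

test_that("pNNx uses strict thresholds and histograms behave", {
  iv <- c(800, 810, 790, 805)      # diffs 10, -20, 15
  s <- interval_series(cumsum(c(1, iv / 1000)), "IBI")
  e <- ecg_extra_stats(s)
  expect_equal(unname(e["pnn50"]), 0)
  iv2 <- c(800, 860, 790, 870)     # diffs 60, -70, 80
  e2 <- ecg_extra_stats(interval_series(cumsum(c(1, iv2 / 1000)), "IBI"))
  expect_equal(unname(e2["pnn50"]), 1)
  # boundary: a difference of exactly 20 ms does not count for pNN20
  iv3 <- c(800, 820, 800, 820, 800)
  e3 <- ecg_extra_stats(interval_series(cumsum(c(1, iv3 / 1000)), "IBI"))
  expect_equal(unname(e3["pnn20"]), 0)

  # 40 intervals spread uniformly over 4 bins, 10 per bin
  bw <- 1000 / 128
  vals <- rep(bw * c(100.5, 101.5, 102.5, 103.5), each = 10)
  s4 <- interval_series(cumsum(c(1, vals / 1000)), "IBI")
  e4 <- ecg_extra_stats(s4)
  expect_equal(unname(e4["hti"]), 4)

  # degenerate one-bin histogram
  s5 <- interval_series(cumsum(c(1, rep(0.8, 12))), "IBI")
  e5 <- ecg_extra_stats(s5)
  expect_equal(unname(e5["tinn"]), 0)
})

test_that("band powers localise sinusoidal interval modulation", {
  hf_mod <- modulated_ibi_series(300, 1000, 50, 0.25)
  sp <- interval_spectral_stats(hf_mod)
  expect_gt(unname(sp["hf"]), 5 * unname(sp["lf"]))
  expect_lt(unname(sp["lf_hf"]), 0.2)

  lf_mod <- modulated_ibi_series(300, 1000, 50, 0.10)
  sp2 <- interval_spectral_stats(lf_mod)
  expect_gt(unname(sp2["lf"]), 5 * unname(sp2["hf"]))

  expect_equal(unname(sp["lnhf"]), log(unname(sp["hf"])))
  # too-short window yields missing sentinels
  short <- random_ibi_series(10)
  expect_true(all(is.na(interval_spectral_stats(short))))
})

test_that("indicators match independent brute-force oracles on random series", {
  set.seed(99)
  for (rep in 1:50) {
    n <- sample(20:200, 1)
    s <- random_ibi_series(n, mean_ms = stats::runif(1, 700, 1100),
                           sd_ms = stats::runif(1, 20, 80))
    iv <- s$intervals
    st <- interval_time_stats(s)
    o <- oracle_time_stats(iv)
    expect_equal(unname(st[names(o)]), unname(o), tolerance = 1e-9)
    p <- poincare_stats(s)
    op <- oracle_poincare(iv)
    expect_equal(unname(p[names(op)]), unname(op), tolerance = 1e-9)
    e <- ecg_extra_stats(s)
    expect_equal(unname(e["pnn50"]), oracle_pnn(iv, 50), tolerance = 1e-12)
    expect_equal(unname(e["pnn20"]), oracle_pnn(iv, 20), tolerance = 1e-12)
  }
})

test_that("algebraic identities hold on random series", {
  set.seed(123)
  for (rep in 1:20) {
    s <- random_ibi_series(sample(30:150, 1))
    st <- interval_time_stats(s)
    p <- poincare_stats(s)
    expect_equal(unname(p["sd1"]), unname(st["rmssd"]) / sqrt(2),
                 tolerance = 1e-12)
    expect_equal(unname(st["cvsd"]), unname(st["rmssd"] / st["mean"]),
                 tolerance = 1e-12)
    expect_equal(unname(st["cv"]), unname(st["sd"] / st["mean"]),
                 tolerance = 1e-12)
    expect_equal(unname(p["csi"]), unname(p["sd2"] / p["sd1"]),
                 tolerance = 1e-12)
    expect_equal(unname(st["mean_rate"] * st["mean"]), 60000,
                 tolerance = 1e-9)
    # shift invariance of short-term variability
    s2 <- interval_series(s$event_times + cumsum(rep(0.1, length(s$event_times))), "IBI")
    st2 <- interval_time_stats(s2)
    p2 <- poincare_stats(s2)
    expect_equal(unname(st2["rmssd"]), unname(st["rmssd"]), tolerance = 1e-9)
    expect_equal(unname(st2["sdsd"]), unname(st["sdsd"]), tolerance = 1e-9)
    expect_equal(unname(p2["sd1"]), unname(p["sd1"]), tolerance = 1e-9)
  }
})

test_that("EDA window statistics are consistent", {
  fs <- 50
  comp <- decompose_eda(rep(2, 60 * fs), fs)
  ind <- eda_stats(comp, 0, 60)
  expect_equal(unname(ind["eda_mean"]), 2, tolerance = 1e-2)
  expect_equal(unname(ind["eda_min"]), unname(ind["eda_max"]),
               tolerance = 1e-2)
  expect_equal(unname(ind["eda_sd"]), 0, tolerance = 1e-3)
  expect_equal(unname(ind["eda_scr_freq"]), 0)
  expect_true(is.na(ind["eda_scr_amp"]))
  expect_true(ind["eda_min"] <= ind["eda_mean"] &&
              ind["eda_mean"] <= ind["eda_max"])
  expect_error(eda_stats(comp, 0, 5), ">= 10 s")
})

test_that("respiratory extras: amplitude, entropy, long-term DFA gate", {
  # sine of amplitude 1 has peak-to-trough 2 per cycle
  fs <- 20
  t <- seq(0, 120 - 1 / fs, by = 1 / fs)
  br <- segment_breaths(sin(2 * pi * 0.25 * t), fs)
  r <- resp_extra_stats(br$cycles, br$bb)
  expect_equal(unname(r["amp_mean"]), 2, tolerance = 0.02)

  # perfectly periodic breath intervals: near-zero entropy
  bb <- interval_series(seq(0, 480, by = 4), "BB")
  r2 <- resp_extra_stats(list(onsets = numeric(0), insp = numeric(0),
                              expir = numeric(0), amplitudes = numeric(0)), bb)
  expect_lt(abs(unname(r2["apen"])), 0.05)
  # a 20-min session at ~15 cycles/min has ~300 cycles: DFA2 unavailable
  expect_true(is.na(r2["dfa2"]))

  # with > 640 cycles DFA2 becomes available
  set.seed(5)
  long_bb <- interval_series(cumsum(c(0, stats::rnorm(700, 4, 0.3))), "BB")
  r3 <- resp_extra_stats(list(onsets = numeric(0), insp = numeric(0),
                              expir = numeric(0), amplitudes = numeric(0)),
                         long_bb)
  expect_true(is.finite(r3["dfa2"]))
})

test_that("peak-to-trough RSA follows the inspiration rule", {
  # constructed cycles: heart periods 1000..1050 in cycle, inspiration
  # holds the shortest (950)
  onsets <- c(0, 4, 8, 12)
  cycles <- list(onsets = onsets[1:3], insp = rep(2, 3), expir = rep(2, 3),
                 amplitudes = rep(1, 3))
  # place beats so each cycle holds two 950 ms periods ending inside the
  # inspiration and a 1050 ms period later in the cycle
  times <- unlist(lapply(onsets[1:3], function(o)
    c(o + 0.05, o + 1.0, o + 1.95, o + 3.0)))
  ibi <- interval_series(times, "IBI")
  r <- rsa_stats(ibi, cycles)
  expect_equal(unname(r["rsa_mean"]), 100, tolerance = 1e-6)
  expect_equal(unname(r["rsa_mean_log"]), log(100), tolerance = 1e-6)

  # constant heart periods: all estimates zero
  const <- interval_series(seq(0.4, 30, by = 0.7), "IBI")
  cyc2 <- list(onsets = c(0, 4, 8, 12, 16), insp = rep(2, 5),
               expir = rep(2, 5), amplitudes = rep(1, 5))
  r2 <- rsa_stats(const, cyc2)
  expect_equal(unname(r2["rsa_mean"]), 0)
  expect_equal(unname(r2["rsa_sd"]), 0)

  # larger simulated RSA gain gives larger peak-to-trough estimates
  est_for_gain <- function(gain, seed) {
    p <- sim_params(rsa_gain = gain, hrv_sdnn = 30, breathing_rate = 12)
    set.seed(seed)
    br <- simulate_breath_cycles(p, 300, fs = 100)
    rpk <- simulate_ibi_series(p, br, 300)
    cyc <- list(onsets = br$onsets[-length(br$onsets)],
                insp = br$insp[-length(br$insp)],
                expir = br$exp[-length(br$exp)],
                amplitudes = br$amplitudes[-length(br$amplitudes)])
    unname(rsa_stats(interval_series(rpk, "IBI"), cyc)["rsa_mean"])
  }
  expect_gt(est_for_gain(100, 31), est_for_gain(50, 31))
})

test_that("the full indicator vector is complete and ordered", {
  cfg <- tiny_config(seed = 2)
  s <- simulate_subject(cfg, "task", 1)
  d <- process_subject(s$recording)
  ind <- compute_indicators(d$driving, 0, cfg$driving_duration)
  expect_equal(length(ind), 61)
  expect_identical(names(ind), indicator_catalog()$name)
  # window indicators for the driving phase of a task subject are mostly
  # defined; DFA2 is structurally missing within a session
  expect_true(is.na(ind["rrv_dfa2"]))
  expect_lt(sum(is.na(ind)), 8)
})

test_that("the MAD convention switch changes only the dispersion pair", {
  s <- random_ibi_series(50)
  a <- interval_time_stats(s, mad_type = "mean_abs_dev")
  b <- interval_time_stats(s, mad_type = "median_abs_dev")
  md <- stats::median(s$intervals)
  expect_equal(unname(a["mad"]), mean(abs(s$intervals - md)))
  expect_equal(unname(b["mad"]), stats::median(abs(s$intervals - md)))
  expect_equal(a[c("mean", "sd", "rmssd")], b[c("mean", "sd", "rmssd")])
})
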