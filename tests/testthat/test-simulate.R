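test_that("breath-cycle generation matches the configured rate", {
  p <- sim_params(breathing_rate = 15, breath_jitter = 0)
  p$noise_sd$resp <- 0
  set.seed(1)
  br <- simulate_breath_cycles(p, 60, fs = 100)
  # deterministic periodic case: 15 cycles of 4000 ms
  expect_equal(length(br$onsets), 15)
  expect_equal(unique(round(diff(br$onsets), 6)), 4)
  expect_equal(length(br$resp), 6000)

  # jittered case: cycle count near rate * duration / 60
  p2 <- sim_params(breathing_rate = 12, breath_jitter = 0.05)
  set.seed(42)
  br2 <- simulate_breath_cycles(p2, 1200, fs = 100)
  expect_lt(abs(length(br2$onsets) - 240), 3 * sqrt(240) * 0.05 * 12)
  # amplitude calibration: per-cycle peak-to-trough ~ breath_amp
  expect_equal(mean(br2$amplitudes), p2$breath_amp, tolerance = 0.05)

  expect_error(simulate_breath_cycles(p, 0), "duration")
  expect_error(sim_params(breathing_rate = -1), "breathing_rate")
})

test_that("IBI generation honours mean rate, RSA gain and jitter", {
  # degenerate case: constant 1000 ms periods
  p0 <- sim_params(mean_hr = 60, hrv_sdnn = 0, rsa_gain = 0)
  set.seed(1)
  rpk <- simulate_ibi_series(p0, NULL, 30)
  expect_equal(unique(round(diff(rpk) * 1000, 9)), 1000)

  # RSA coupling: per-cycle IBI range close to the configured gain
  p1 <- sim_params(mean_hr = 75, hrv_sdnn = 36, rsa_gain = 100,
                   breathing_rate = 15, breath_jitter = 0)
  set.seed(2)
  br <- simulate_breath_cycles(p1, 300, fs = 100)
  rpk1 <- simulate_ibi_series(p1, br, 300)
  ibis <- diff(rpk1) * 1000
  mids <- rpk1[-1]
  cyc <- findInterval(mids, br$onsets)
  rng <- tapply(ibis, cyc, function(v) max(v) - min(v))
  rng <- rng[tapply(ibis, cyc, length) >= 4]
  # beats sample the sinusoid discretely, so the observed range sits just
  # below the configured peak-to-trough gain
  expect_gt(mean(rng), 0.6 * 100)
  expect_lt(mean(rng), 1.35 * 100)

  # task defaults shorten the mean IBI relative to control
  ctrl <- sim_params(); task <- task_params(ctrl)
  set.seed(3); ib_c <- mean(diff(simulate_ibi_series(ctrl, NULL, 120)))
  set.seed(3); ib_t <- mean(diff(simulate_ibi_series(task, NULL, 120)))
  expect_lt(ib_t, ib_c)

  bad <- sim_params(); bad$mean_hr <- -10
  expect_error(simulate_ibi_series(bad, NULL, 10), "mean_hr")
})

test_that("ECG rendering places one R deflection per peak time", {
  x <- render_ecg(c(1, 2, 3), 4, 1000, 0)
  expect_equal(which.max(x[501:1500]) + 500, 1001)
  expect_equal(which.max(x[1501:2500]) + 1500, 2001)
  expect_equal(which.max(x[2501:3500]) + 2500, 3001)
  expect_equal(render_ecg(numeric(0), 2, 1000, 0), numeric(2000))
  expect_error(render_ecg(c(2, 1), 3, 1000), "increasing")
})

test_that("EDA simulation follows the tonic + SCR + noise model", {
  p <- sim_params(scr_rate = 0, eda_tonic_drift_sd = 0, eda_tonic_level = 2)
  p$noise_sd$eda <- 0
  set.seed(1)
  e <- simulate_eda(p, 60, fs = 100)
  expect_equal(unique(round(e$eda, 9)), 2)

  # task defaults raise the mean level
  set.seed(4); e_c <- mean(simulate_eda(sim_params(), 120, 100)$eda)
  set.seed(4); e_t <- mean(simulate_eda(task_params(), 120, 100)$eda)
  expect_gt(e_t, e_c)

  bad <- sim_params(); bad$scr_rate <- -1
  expect_error(simulate_eda(bad, 10), "scr_rate")
})

test_that("subject simulation spans both phases and is reproducible", {
  cfg <- tiny_config(seed = 11)
  s <- simulate_subject(cfg, "task", 1)
  n_exp <- (cfg$baseline_duration + cfg$driving_duration) * cfg$sampling_rate
  expect_equal(length(s$recording$ecg), n_exp)
  expect_equal(length(s$recording$eda), n_exp)
  expect_equal(length(s$recording$resp), n_exp)
  expect_equal(s$recording$phases$end[2], 180)

  s2 <- simulate_subject(cfg, "task", 1)
  expect_identical(s$recording$ecg, s2$recording$ecg)
  expect_identical(s$truth$driving$scr_event_times,
                   s2$truth$driving$scr_event_times)

  # task condition raises driving heart rate above own baseline
  hr_of <- function(tr, dur) 60 * length(tr$r_peak_times) / dur
  expect_gt(hr_of(s$truth$driving, cfg$driving_duration),
            hr_of(s$truth$baseline, cfg$baseline_duration))
})

test_that("cohorts are balanced, labelled and seed-reproducible", {
  cfg <- tiny_config(seed = 5, baseline = 40, driving = 40)
  # use the callback form to keep only labels
  labs <- unlist(simulate_cohort(6, cfg, fun = function(s) s$recording$condition))
  expect_equal(sum(labs == "task"), 3)
  labs3 <- unlist(simulate_cohort(3, cfg, fun = function(s) s$recording$condition))
  expect_equal(sum(labs3 == "task"), 2)
  expect_equal(sum(labs3 == "control"), 1)
  expect_error(simulate_cohort(1, cfg), "at least 2")

  a <- simulate_cohort(2, cfg, fun = function(s) s$recording$eda[1:100])
  b <- simulate_cohort(2, cfg, fun = function(s) s$recording$eda[1:100])
  expect_identical(a, b)
})

test_that("ground-truth event times are valid", {
  s <- simulate_subject(tiny_config(seed = 9), "control", 2)
  for (ph in c("baseline", "driving")) {
    tr <- s$truth[[ph]]
    expect_true(all(diff(tr$r_peak_times) > 0))
    expect_true(all(diff(tr$breath_onset_times) > 0))
    expect_true(all(tr$scr_amplitudes > 0))
    dur <- if (ph == "baseline") 60 else 120
    expect_true(all(tr$r_peak_times >= 0 & tr$r_peak_times <= dur))
    expect_true(all(tr$scr_event_times >= 0 & tr$scr_event_times <= dur))
  }
})

test_that("widening the task-control gap increases mean-rate separability", {
  f_of_gap <- function(d_hr, seed) {
    ctrl <- sim_params()
    cfg <- sim_config(baseline_duration = 60, driving_duration = 60,
                      control_params = ctrl,
                      task_params = task_params(ctrl, d_hr = d_hr),
                      seed = seed)
    ds <- cohort_dataset(12, cfg, levels = 1)
    fm <- engineer_features(ds$windows, ds$baseline, c("EDA", "ECG", "RESP"))
    sel <- anova_select(fm$x[, "hrv_mean_rate_win", drop = FALSE], fm$y,
                        alpha = 1, on_empty = "silent")
    sel$f[["hrv_mean_rate_win"]]
  }
  fs <- vapply(c(1, 7, 20), function(g)
    mean(vapply(1:2, function(sd) f_of_gap(g, sd), numeric(1))), numeric(1))
  expect_true(all(diff(fs) > 0))
})
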