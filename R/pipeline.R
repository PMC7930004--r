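#' Preprocess a raw recording into derived series
#'
#' Runs the per-phase preprocessing chain: ECG band-pass and R-peak
#' detection; EDA downsampling/filtering, convex tonic/phasic decomposition
#' and SCR detection; respiration downsampling (to 20 Hz), band-pass,
#' smoothing and breath segmentation. Phases are processed separately and
#' all derived series use phase-relative time.
#'
#' @param recording A `raw_recording` (see [simulate_subject()] or
#'   [read_recording()]).
#' @param scr_amp_min SCR amplitude criterion (uS).
#' @return Named list with one entry per phase, each a list `ibi`, `bb`,
#'   `cycles`, `eda` (an `eda_components`).
#' @export
process_subject <- function(recording, scr_amp_min = 0.05) {
  fs <- recording$sampling_rate
  out <- list()
  for (i in seq_len(nrow(recording$phases))) {
    ph <- recording$phases$phase[i]
    sl <- (round(recording$phases$start[i] * fs) + 1):
      round(recording$phases$end[i] * fs)
    ecg_f <- filter_ecg(recording$ecg[sl], fs)
    ibi <- detect_r_peaks(ecg_f, fs)

    eda_f <- preprocess_eda(recording$eda[sl], fs)
    comp <- decompose_eda(as.numeric(eda_f), attr(eda_f, "fs"),
                          scr_amp_min = scr_amp_min)

    fs_resp <- if (fs >= 40 && fs %% 20 == 0) 20 else fs
    resp <- if (fs_resp < fs) decimate_mean(recording$resp[sl], fs %/% 20)
            else recording$resp[sl]
    # cycle segmentation runs on the band-passed signal without the 3 s box
    # smoother: that window's first spectral null (1/3 Hz) sits inside the
    # physiological breathing range and can erase fast breathers entirely
    resp_f <- preprocess_resp(resp, fs_resp, smooth = FALSE)
    br <- segment_breaths(resp_f, fs_resp)

    out[[ph]] <- list(ibi = ibi, bb = br$bb, cycles = br$cycles, eda = comp)
  }
  out
}

#' Indicator tables for one subject at one or more segmentation levels
#'
#' Baseline indicators are computed once over the full baseline phase
#' regardless of segmentation level; driving-phase indicators are computed
#' per window for every requested level.
#'
#' @param recording A `raw_recording`.
#' @param levels Integer vector of segmentation levels.
#' @param derived Optional precomputed result of [process_subject()].
#' @return List with `windows` (data frame: `subject_id`, `condition`,
#'   `level`, `window`, 61 indicator columns) and `baseline` (one row:
#'   `subject_id` plus indicators).
#' @export
subject_indicators <- function(recording, levels = c(1, 2, 5, 10, 20, 40),
                               derived = NULL) {
  if (is.null(derived)) derived <- process_subject(recording)
  base_dur <- diff(unlist(
    recording$phases[recording$phases$phase == "baseline", c("start", "end")]))
  drive_dur <- diff(unlist(
    recording$phases[recording$phases$phase == "driving", c("start", "end")]))

  base_ind <- compute_indicators(derived$baseline, 0, base_dur)
  rows <- list()
  for (L in levels) {
    wins <- split_windows(drive_dur, L)
    for (w in seq_len(nrow(wins))) {
      ind <- compute_indicators(derived$driving, wins$start[w], wins$end[w])
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = recording$subject_id,
        condition = recording$condition,
        level = L, window = w,
        as.list(ind), check.names = FALSE)
    }
  }
  list(windows = do.call(rbind, rows),
       baseline = data.frame(subject_id = recording$subject_id,
                             as.list(base_ind), check.names = FALSE))
}

#' Simulate and preprocess a full cohort into indicator tables
#'
#' Memory-safe driver: each subject is simulated, preprocessed and reduced
#' to indicator rows before the raw channels are discarded.
#'
#' @param n Number of subjects.
#' @param config A [sim_config()].
#' @param levels Segmentation levels to compute.
#' @param verbose Print progress.
#' @return List with `windows` and `baseline` data frames (stacked over
#'   subjects), ready for [engineer_features()] / [evaluate_design()].
#' @export
cohort_dataset <- function(n, config = sim_config(),
                           levels = c(1, 2, 5, 10, 20, 40),
                           verbose = FALSE) {
  parts <- simulate_cohort(n, config, fun = function(s)
    subject_indicators(s$recording, levels), verbose = verbose)
  list(windows = do.call(rbind, lapply(parts, `[[`, "windows")),
       baseline = do.call(rbind, lapply(parts, `[[`, "baseline")))
}

#' Run the full classification pipeline and write a results bundle
#'
#' Simulates (or accepts) a cohort indicator dataset, evaluates the design
#' grid (sensor selections x segmentation levels x classifiers) with
#' ANOVA-selected, cross-validated classification, and writes the evaluation
#' table and a JSON report to `out_dir`.
#'
#' @param n Number of subjects (ignored when `dataset` is given).
#' @param config A [sim_config()].
#' @param dataset Optional precomputed [cohort_dataset()].
#' @param levels,selections,classifiers Design axes; see [evaluate_design()].
#' @param grid Hyperparameter grid (see [grid_stage2()], [grid_reduced()]).
#' @param out_dir Output directory; created if missing. `NULL` skips writing.
#' @param seed Seed for fold assignment.
#' @param ... Passed to [evaluate_design()].
#' @return The evaluation data frame, invisibly when writing.
#' @export
run_pipeline <- function(n = 90, config = sim_config(), dataset = NULL,
                         levels = c(1, 2, 5, 10, 20, 40),
                         selections = all_selections(),
                         classifiers = c("RF", "SVC", "MLP"),
                         grid = grid_reduced(), out_dir = NULL, seed = 1, ...) {
  if (is.null(dataset)) dataset <- cohort_dataset(n, config, levels)
  res <- evaluate_design(dataset, selections = selections, levels = levels,
                         classifiers = classifiers, grid = grid, seed = seed,
                         ...)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(res, file.path(out_dir, "evaluation.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(seed = seed, n_rows = nrow(res), results = res),
      file.path(out_dir, "evaluation.json"), auto_unbox = TRUE, digits = NA)
    invisible(res)
  } else res
}
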