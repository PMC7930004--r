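#' Write a recording to CSV with a JSON manifest
#'
#' The channel file has columns `time_s, ecg, eda, resp` (6-decimal
#' precision); the sidecar manifest (`<stem>_manifest.json`) records the
#' sampling rate, phase annotations, subject id and condition label.
#'
#' @param recording A `raw_recording`.
#' @param path Output CSV path; the manifest is written next to it.
#' @param digits Numeric precision (decimal places).
#' @return Invisibly, the two paths written.
#' @export
write_recording <- function(recording, path, digits = 6) {
  n <- length(recording$ecg)
  fs <- recording$sampling_rate
  df <- data.frame(time_s = round((seq_len(n) - 1) / fs, digits),
                   ecg = round(recording$ecg, digits),
                   eda = round(recording$eda, digits),
                   resp = round(recording$resp, digits))
  utils::write.csv(df, path, row.names = FALSE)
  man <- list(sampling_rate = fs,
              subject_id = recording$subject_id,
              condition = recording$condition,
              phases = recording$phases)
  man_path <- sub("\\.csv$", "_manifest.json", path)
  jsonlite::write_json(man, man_path, auto_unbox = TRUE, digits = NA)
  invisible(c(path, man_path))
}

#' Read a recording from CSV and its JSON manifest
#'
#' @param path CSV path written by [write_recording()] (columns `time_s`,
#'   `ecg`, `eda`, `resp`); the manifest is looked up as
#'   `<stem>_manifest.json` unless given.
#' @param manifest Optional manifest path.
#' @return A `raw_recording`.
#' @export
read_recording <- function(path, manifest = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (is.null(manifest)) manifest <- sub("\\.csv$", "_manifest.json", path)
  if (!file.exists(manifest))
    stop("no manifest found at ", manifest, call. = FALSE)
  df <- utils::read.csv(path)
  missing_ch <- setdiff(c("ecg", "eda", "resp"), names(df))
  if (length(missing_ch))
    stop("recording is missing channel(s): ",
         paste(missing_ch, collapse = ", "), call. = FALSE)
  man <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  fs <- man$sampling_rate
  dur <- nrow(df) / fs
  phases <- as.data.frame(man$phases)
  if (any(phases$end > dur + 1e-9) || any(phases$start < 0))
    stop("manifest phases extend beyond the recording span", call. = FALSE)
  if (nrow(phases) > 1 &&
      any(phases$start[-1] < phases$end[-nrow(phases)] - 1e-9))
    stop("manifest phases overlap", call. = FALSE)
  rec <- list(ecg = df$ecg, eda = df$eda, resp = df$resp,
              sampling_rate = fs, phases = phases,
              subject_id = man$subject_id, condition = man$condition)
  class(rec) <- "raw_recording"
  rec
}
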