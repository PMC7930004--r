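#' Split a session phase into equal contiguous windows
#'
#' @param duration Phase duration (s).
#' @param level Number of windows (the segmentation level); any positive
#'   integer, typically 1, 2, 5, 10, 20 or 40.
#' @return Data frame with `index`, `start`, `end`; windows tile the phase
#'   exactly with no gaps or overlaps.
#' @export
split_windows <- function(duration, level) {
  if (!is.numeric(level) || level <= 0 || level != round(level))
    stop("segmentation level must be a positive integer", call. = FALSE)
  edges <- seq(0, duration, length.out = level + 1)
  data.frame(index = seq_len(level),
             start = edges[-length(edges)],
             end = edges[-1])
}

# Indicator names for a sensor selection. RSA indicators require both parent
# signals (ECG and RESP).
selection_indicators <- function(selection) {
  selection <- match.arg(selection, c("EDA", "ECG", "RESP"), several.ok = TRUE)
  cat <- indicator_catalog()
  signals <- selection
  if (all(c("ECG", "RESP") %in% selection)) signals <- c(signals, "RSA")
  cat$name[cat$signal %in% signals]
}

#' Assemble window and baseline-delta features
#'
#' For every indicator of the selected signals, two features are emitted:
#' the window value (`_win`) and the difference between the window value and
#' the subject's baseline value (`_delta`). With all three signals selected
#' this yields 122 columns. Respiratory-sinus-arrhythmia indicators are
#' included only when both ECG and RESP are selected.
#'
#' @param window_indicators Data frame, one row per (subject, window), with
#'   metadata columns (`subject_id`, `condition`, `window`) and the 61
#'   indicator columns.
#' @param baseline_indicators Data frame, one row per subject, with
#'   `subject_id` and the 61 indicator columns (computed once over the full
#'   baseline).
#' @param selection Character subset of `c("EDA", "ECG", "RESP")`; must be
#'   non-empty.
#' @return List with `x` (numeric feature matrix), `y` (factor
#'   control/task), `meta` (data frame `subject_id`, `window`).
#' @export
engineer_features <- function(window_indicators, baseline_indicators,
                              selection = c("EDA", "ECG", "RESP")) {
  if (length(selection) == 0) stop("empty signal selection", call. = FALSE)
  inds <- selection_indicators(selection)
  key <- match(window_indicators$subject_id, baseline_indicators$subject_id)
  if (anyNA(key)) stop("missing baseline rows for some subjects", call. = FALSE)
  win <- as.matrix(window_indicators[, inds, drop = FALSE])
  base <- as.matrix(baseline_indicators[key, inds, drop = FALSE])
  x <- cbind(win, win - base)
  colnames(x) <- c(paste0(inds, "_win"), paste0(inds, "_delta"))
  meta <- window_indicators[, c("subject_id", "window")]
  if (anyDuplicated(meta)) stop("duplicated (subject, window) rows", call. = FALSE)
  list(x = x,
       y = factor(window_indicators$condition, levels = c("control", "task")),
       meta = meta)
}

#' Min-max normalisation learned on a row subset
#'
#' Per-column minimum and maximum are learned on `fit_rows` only and the
#' affine transform is applied to all rows; values from the fitted rows land
#' in \[0, 1\], held-out values may fall outside and are not clipped.
#' Constant columns map to 0.
#'
#' @param x Numeric matrix.
#' @param fit_rows Row indices used to learn the scaling (default: all).
#' @return Matrix of the same shape with attributes `min` and `range`.
#' @export
minmax_normalize <- function(x, fit_rows = seq_len(nrow(x))) {
  if (length(fit_rows) == 0) stop("fit_rows must be non-empty", call. = FALSE)
  mn <- apply(x[fit_rows, , drop = FALSE], 2, min, na.rm = TRUE)
  mx <- apply(x[fit_rows, , drop = FALSE], 2, max, na.rm = TRUE)
  rg <- mx - mn
  const <- !is.finite(rg) | rg == 0
  if (any(const)) {
    warning(sum(const), " constant feature column(s) mapped to 0")
    rg[const] <- 1
    mn[const] <- 0
    x[, const] <- 0
  }
  out <- sweep(sweep(x, 2, mn, "-"), 2, rg, "/")
  attr(out, "min") <- mn
  attr(out, "range") <- rg
  out
}
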