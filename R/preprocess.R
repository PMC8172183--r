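#' Preprocessing configuration
#'
#' Defaults follow the pipeline's signal-conditioning convention: a 1 Hz
#' high-pass and a 50 Hz low-pass IIR filter (each a 4th-order Butterworth
#' section applied forward-backward for zero phase), downsampling to 250 Hz,
#' and non-overlapping 1-second analysis windows.
#'
#' @param hp_cut High-pass cutoff in Hz.
#' @param lp_cut Low-pass cutoff in Hz.
#' @param target_fs Output sampling rate in Hz.
#' @param window_s Analysis-window length in seconds.
#' @param filter_order Order of each Butterworth section.
#' @return A list of class `preprocess_config`.
#' @export
preprocess_config <- function(hp_cut = 1, lp_cut = 50, target_fs = 250,
                              window_s = 1, filter_order = 4) {
  if (!(hp_cut > 0 && hp_cut < lp_cut && lp_cut <= target_fs / 2)) {
    abort("need 0 < hp_cut < lp_cut <= target_fs / 2")
  }
  if (window_s <= 0) abort("`window_s` must be positive")
  structure(
    list(hp_cut = hp_cut, lp_cut = lp_cut, target_fs = target_fs,
         window_s = window_s, filter_order = filter_order),
    class = "preprocess_config"
  )
}

#' Band-limit and resample a recording
#'
#' Applies the high-pass then the low-pass Butterworth section, each
#' forward-backward (zero phase), then resamples to `cfg$target_fs`.
#' Filtering always precedes resampling so the low-pass doubles as the
#' anti-alias filter. Integer downsampling factors use plain decimation of the
#' already band-limited signal; non-integer ratios fall back to polyphase
#' resampling.
#'
#' @param rec An [eeg_recording()] with `fs >= 2 * cfg$lp_cut`.
#' @param cfg A [preprocess_config()].
#' @return An [eeg_recording()] at `cfg$target_fs`.
#' @export
bandlimit_resample <- function(rec, cfg = preprocess_config()) {
  if (!is_eeg_recording(rec)) abort("`rec` must be an eeg_recording")
  if (rec$fs < 2 * cfg$lp_cut) {
    abort(sprintf("fs = %g Hz violates the Nyquist bound for lp_cut = %g Hz",
                  rec$fs, cfg$lp_cut))
  }
  hp <- signal::butter(cfg$filter_order, cfg$hp_cut / (rec$fs / 2), type = "high")
  lp <- signal::butter(cfg$filter_order, cfg$lp_cut / (rec$fs / 2), type = "low")
  filt <- t(apply(rec$data, 1, function(x) {
    signal::filtfilt(lp, signal::filtfilt(hp, x))
  }))
  rownames(filt) <- rownames(rec$data)

  if (rec$fs == cfg$target_fs) {
    out <- filt
  } else if (rec$fs %% cfg$target_fs == 0) {
    by <- rec$fs / cfg$target_fs
    out <- filt[, seq(1, ncol(filt), by = by), drop = FALSE]
  } else {
    frac <- MASS::fractions(cfg$target_fs / rec$fs)
    pq <- as.integer(strsplit(attr(frac, "fracs"), "/")[[1]])
    if (length(pq) == 1) pq <- c(pq, 1L)
    out <- t(apply(filt, 1, function(x) signal::resample(x, pq[1], pq[2])))
    rownames(out) <- rownames(rec$data)
  }
  res <- rec
  res$data <- out
  res$fs <- cfg$target_fs
  res
}

#' Baseline-correct a recording
#'
#' Subtracts, per channel, the mean of the baseline recording from the task
#' recording (DC-offset removal in the signal domain). Correcting the baseline
#' recording by itself makes each of its channels zero-mean.
#'
#' @param task,baseline [eeg_recording()]s with identical channels and
#'   sampling rate.
#' @return The corrected task recording.
#' @export
baseline_correct <- function(task, baseline) {
  if (!identical(rownames(task$data), rownames(baseline$data))) {
    abort("task and baseline recordings must have identical channels")
  }
  if (task$fs != baseline$fs) abort("task and baseline sampling rates differ")
  out <- task
  out$data <- task$data - rowMeans(baseline$data)
  out
}

#' Split a recording into fixed-length windows
#'
#' Non-overlapping, contiguous, order-preserving windows of `cfg$window_s`
#' seconds; a trailing partial window is dropped.
#'
#' @param rec An [eeg_recording()].
#' @param cfg A [preprocess_config()] (only `window_s` is used).
#' @return An `eeg_windows` object: the recording metadata plus a channels x
#'   samples x n_windows array.
#' @export
window_recording <- function(rec, cfg = preprocess_config()) {
  wlen <- round(cfg$window_s * rec$fs)
  n_win <- floor(ncol(rec$data) / wlen)
  if (n_win < 1) abort("recording is shorter than one window")
  used <- rec$data[, seq_len(n_win * wlen), drop = FALSE]
  arr <- array(used, dim = c(nrow(used), wlen, n_win),
               dimnames = list(rownames(rec$data), NULL, NULL))
  structure(
    list(subject_id = rec$subject_id, group = rec$group,
         condition = rec$condition, fs = rec$fs, window_s = cfg$window_s,
         channels = rownames(rec$data), windows = arr,
         window_index = seq_len(n_win) - 1L),
    class = "eeg_windows"
  )
}

#' @export
print.eeg_windows <- function(x, ...) {
  cat(sprintf("<eeg_windows> %s/%s %s: %d windows of %d ch x %d samples @ %g Hz\n",
              x$subject_id, x$group, x$condition, n_windows(x),
              dim(x$windows)[1], dim(x$windows)[2], x$fs))
  invisible(x)
}

#' Number of windows in an `eeg_windows` object
#' @param wrec An `eeg_windows` object.
#' @return Integer window count.
#' @export
n_windows <- function(wrec) dim(wrec$windows)[3]

#' Time-window partition of each task
#'
#' Each task's window sequence is split into three 200-window slices. For the
#' 600-window baseline and preparation tasks the slices are `[0, 200)`,
#' `[200, 400)` and `[400, 600)`. The 300-window speech and arithmetic tasks
#' use `[0, 200)` for slice 1 and `[100, 300)` for both slices 2 and 3 (the
#' two are identical by construction). Indices are 0-based, half-open.
#'
#' @param index Partition index: 1, 2 or 3.
#' @param ranges Optional override: a named list mapping each condition to a
#'   `c(start, end)` half-open window-index range.
#' @return A list of class `time_window_partition` with elements `index` and
#'   `ranges`.
#' @export
time_window_partition <- function(index, ranges = NULL) {
  if (!index %in% 1:3) abort("`index` must be 1, 2 or 3")
  if (is.null(ranges)) {
    long <- list(c(0, 200), c(200, 400), c(400, 600))[[index]]
    short <- list(c(0, 200), c(100, 300), c(100, 300))[[index]]
    ranges <- list(baseline = long, preparation = long,
                   speech = short, arithmetic = short)
  }
  structure(list(index = index, ranges = ranges),
            class = "time_window_partition")
}

#' Select the partition slice of a windowed recording
#'
#' @param wrec An `eeg_windows` object.
#' @param part A [time_window_partition()].
#' @return An `eeg_windows` object containing exactly the windows in the
#'   condition's range; `window_index` keeps the original 0-based indices.
#' @export
select_time_window <- function(wrec, part) {
  rng <- part$ranges[[wrec$condition]]
  if (is.null(rng)) abort(sprintf("partition has no range for condition '%s'", wrec$condition))
  if (rng[2] > n_windows(wrec)) {
    abort(sprintf("condition '%s' has %d windows; partition %d needs [%d, %d)",
                  wrec$condition, n_windows(wrec), part$index, rng[1], rng[2]))
  }
  keep <- (rng[1] + 1):rng[2]
  out <- wrec
  out$windows <- wrec$windows[, , keep, drop = FALSE]
  out$window_index <- wrec$window_index[keep]
  out
}

#' Reject high-amplitude windows
#'
#' Optional artifact hook (off by default in the pipeline): drops windows
#' whose peak absolute amplitude exceeds a threshold.
#'
#' @param wrec An `eeg_windows` object.
#' @param threshold_uv Peak-amplitude threshold in microvolts.
#' @return An `eeg_windows` object with offending windows removed.
#' @export
reject_windows <- function(wrec, threshold_uv = Inf) {
  peak <- apply(abs(wrec$windows), 3, max)
  keep <- peak <= threshold_uv
  out <- wrec
  out$windows <- wrec$windows[, , keep, drop = FALSE]
  out$window_index <- wrec$window_index[keep]
  out
}

#' Preprocess a whole cohort to partition-sliced windows
#'
#' Convenience wrapper chaining [bandlimit_resample()], [baseline_correct()]
#' (each task against the subject's baseline; the baseline against itself),
#' [window_recording()] and [select_time_window()] over a cohort tibble.
#'
#' @param cohort A cohort tibble from [synth_cohort()] or [read_cohort_edf()].
#' @param cfg A [preprocess_config()].
#' @param part A [time_window_partition()].
#' @return The cohort tibble with the `recording` column replaced by a
#'   `windows` list-column of `eeg_windows`.
#' @export
preprocess_cohort <- function(cohort, cfg = preprocess_config(),
                              part = time_window_partition(3)) {
  conditioned <- cohort |>
    mutate(recording = map(.data$recording, bandlimit_resample, cfg = cfg))
  out <- conditioned |>
    group_by(.data$subject_id) |>
    mutate(windows = {
      base <- .data$recording[[which(.data$condition == "baseline")]]
      map(.data$recording, function(r) {
        r |>
          baseline_correct(base) |>
          window_recording(cfg) |>
          select_time_window(part)
      })
    }) |>
    ungroup()
  select(out, -"recording")
}
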