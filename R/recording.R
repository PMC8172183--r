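#' EEG recording objects
#'
#' An `eeg_recording` holds one labelled multi-channel EEG segment: a
#' channels-by-samples amplitude matrix in microvolts plus the metadata the
#' pipeline carries through every stage (subject, group, condition, sampling
#' rate, generator seed).
#'
#' @param data Numeric matrix, channels x samples, in microvolts. Row names
#'   are the channel labels; `Fz`, `Cz` and `Pz` must be present.
#' @param fs Sampling rate in Hz.
#' @param subject_id Subject identifier.
#' @param group `"nurse"` or `"control"`.
#' @param condition One of `"baseline"`, `"preparation"`, `"speech"`,
#'   `"arithmetic"`.
#' @param seed Integer seed the data was generated from (`NA` for real data).
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, subject_id, group, condition, seed = NA_integer_) {
  if (!is.matrix(data) || !is.numeric(data)) abort("`data` must be a numeric matrix")
  if (is.null(rownames(data))) abort("`data` must have channel labels as row names")
  ch <- rownames(data)
  if (anyDuplicated(ch)) abort("channel labels must be unique")
  if (!all(c("Fz", "Cz", "Pz") %in% ch)) {
    abort("channels must include Fz, Cz and Pz")
  }
  if (!all(is.finite(data))) abort("recording contains non-finite values")
  if (!is.numeric(fs) || length(fs) != 1 || fs <= 0) abort("`fs` must be a positive scalar")
  condition <- match.arg(condition, c("baseline", "preparation", "speech", "arithmetic"))
  group <- match.arg(group, c("nurse", "control"))
  structure(
    list(
      subject_id = as.character(subject_id), group = group, condition = condition,
      fs = fs, channels = ch, data = data, seed = seed
    ),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %s/%s %s: %d ch x %d samples @ %g Hz (%.1f s)\n",
    x$subject_id, x$group, x$condition, nrow(x$data), ncol(x$data), x$fs,
    ncol(x$data) / x$fs
  ))
  invisible(x)
}

#' @rdname eeg_recording
#' @param x Object to test.
#' @export
is_eeg_recording <- function(x) inherits(x, "eeg_recording")

#' Duration of a recording in seconds
#' @param rec An [eeg_recording()].
#' @return Duration in seconds.
#' @export
recording_duration <- function(rec) ncol(rec$data) / rec$fs
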