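# Minimal EDF (European Data Format) I/O.
#
# Implements the classic EDF layout: a 256-byte fixed header, 256 bytes per
# signal of signal headers, then data records of 16-bit little-endian integers
# with per-signal physical/digital scaling. One data record per second. This
# covers what the pipeline needs (equal sampling rate across channels, one
# condition per file); EDF+ annotations are not implemented — condition and
# group travel in the 80-character recording-identification field.

pad_ascii <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

#' Write a recording to an EDF file
#'
#' Samples are scaled to the full 16-bit digital range of the channel's
#' physical min/max, so the round-trip error is bounded by half a quantization
#' step. Subject id goes in the patient field; `group` and `condition` are
#' stored in the recording-identification field as `group=... condition=...`.
#'
#' @param rec An [eeg_recording()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @seealso [read_edf()]
#' @export
write_edf <- function(rec, path) {
  if (!is_eeg_recording(rec)) abort("`rec` must be an eeg_recording")
  fs <- rec$fs
  if (fs != round(fs)) abort("EDF writer requires an integer sampling rate")
  n_ch <- nrow(rec$data)
  n_samp <- ncol(rec$data)
  n_rec <- floor(n_samp / fs)
  if (n_rec < 1) abort("recording shorter than one EDF data record (1 s)")
  used <- n_rec * fs

  phys_min <- apply(rec$data[, seq_len(used), drop = FALSE], 1, min)
  phys_max <- apply(rec$data[, seq_len(used), drop = FALSE], 1, max)
  flat <- phys_max - phys_min < 1e-9
  phys_max[flat] <- phys_min[flat] + 1 # avoid zero scale for constant channels

  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(pad_ascii("0", 8), con, eos = NULL)
  writeChar(pad_ascii(rec$subject_id, 80), con, eos = NULL)
  writeChar(pad_ascii(sprintf("group=%s condition=%s", rec$group, rec$condition), 80),
            con, eos = NULL)
  writeChar(pad_ascii("01.01.00", 8), con, eos = NULL)
  writeChar(pad_ascii("00.00.00", 8), con, eos = NULL)
  writeChar(pad_ascii(256 * (1 + n_ch), 8), con, eos = NULL)
  writeChar(pad_ascii("", 44), con, eos = NULL)
  writeChar(pad_ascii(n_rec, 8), con, eos = NULL)
  writeChar(pad_ascii(1, 8), con, eos = NULL)
  writeChar(pad_ascii(n_ch, 4), con, eos = NULL)
  for (ch in rownames(rec$data)) writeChar(pad_ascii(ch, 16), con, eos = NULL)
  for (i in seq_len(n_ch)) writeChar(pad_ascii("AgAgCl electrode", 80), con, eos = NULL)
  for (i in seq_len(n_ch)) writeChar(pad_ascii("uV", 8), con, eos = NULL)
  for (i in seq_len(n_ch)) writeChar(pad_ascii(sprintf("%.8g", phys_min[i]), 8), con, eos = NULL)
  for (i in seq_len(n_ch)) writeChar(pad_ascii(sprintf("%.8g", phys_max[i]), 8), con, eos = NULL)
  for (i in seq_len(n_ch)) writeChar(pad_ascii(-32768, 8), con, eos = NULL)
  for (i in seq_len(n_ch)) writeChar(pad_ascii(32767, 8), con, eos = NULL)
  for (i in seq_len(n_ch)) writeChar(pad_ascii("", 80), con, eos = NULL)
  for (i in seq_len(n_ch)) writeChar(pad_ascii(fs, 8), con, eos = NULL)

  scale <- (32767 - (-32768)) / (phys_max - phys_min)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1) * fs + 1):(r * fs)
    for (i in seq_len(n_ch)) {
      dig <- round((rec$data[i, idx] - phys_min[i]) * scale[i]) - 32768
      writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con,
               size = 2, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF file written by [write_edf()]
#'
#' @param path EDF file path.
#' @return An [eeg_recording()].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) trimws(readChar(con, n, useBytes = TRUE))
  version <- rd(8)
  if (version != "0") abort("not an EDF file (bad version field)")
  subject_id <- rd(80)
  rec_id <- rd(80)
  rd(8); rd(8); rd(8); rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  n_ch <- as.integer(rd(4))
  labels <- vapply(seq_len(n_ch), function(i) rd(16), character(1))
  for (i in seq_len(n_ch)) rd(80)
  for (i in seq_len(n_ch)) rd(8)
  phys_min <- vapply(seq_len(n_ch), function(i) as.numeric(rd(8)), numeric(1))
  phys_max <- vapply(seq_len(n_ch), function(i) as.numeric(rd(8)), numeric(1))
  dig_min <- vapply(seq_len(n_ch), function(i) as.numeric(rd(8)), numeric(1))
  dig_max <- vapply(seq_len(n_ch), function(i) as.numeric(rd(8)), numeric(1))
  for (i in seq_len(n_ch)) rd(80)
  spr <- vapply(seq_len(n_ch), function(i) as.integer(rd(8)), integer(1))
  fs <- spr / rec_dur
  if (length(unique(fs)) != 1) abort("mixed sampling rates are not supported")
  fs <- fs[1]

  data <- matrix(0, nrow = n_ch, ncol = n_rec * spr[1],
                 dimnames = list(labels, NULL))
  scale <- (phys_max - phys_min) / (dig_max - dig_min)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(n_ch)) {
      dig <- readBin(con, "integer", n = spr[i], size = 2,
                     endian = "little", signed = TRUE)
      data[i, ((r - 1) * spr[i] + 1):(r * spr[i])] <-
        (dig - dig_min[i]) * scale[i] + phys_min[i]
    }
  }

  m <- regmatches(rec_id, regexec("group=(\\S+) condition=(\\S+)", rec_id))[[1]]
  if (length(m) != 3) abort("recording field lacks group=/condition= annotations")
  eeg_recording(data, fs, subject_id, group = m[2], condition = m[3])
}

#' Write a cohort to EDF files plus a CSV manifest
#'
#' One EDF file per recording, named `<subject>_<condition>.edf`, and a
#' `manifest.csv` with columns `subject_id`, `group`, `condition`, `path`,
#' `seed`.
#'
#' @param cohort A cohort tibble from [synth_cohort()].
#' @param dir Output directory (created if needed).
#' @return The manifest tibble, invisibly.
#' @export
write_cohort_edf <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- cohort |>
    mutate(
      path = file.path(dir, paste0(.data$subject_id, "_", .data$condition, ".edf"))
    )
  purrr::walk2(manifest$recording, manifest$path, write_edf)
  manifest <- select(manifest, "subject_id", "group", "condition", "path", "seed")
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a cohort back from a manifest directory
#'
#' @param dir Directory containing `manifest.csv` and the EDF files written by
#'   [write_cohort_edf()].
#' @return A cohort tibble (`subject_id`, `group`, `condition`, `seed`,
#'   `recording`).
#' @export
read_cohort_edf <- function(dir) {
  manifest <- as_tibble(utils::read.csv(file.path(dir, "manifest.csv")))
  manifest |>
    mutate(recording = map(.data$path, read_edf)) |>
    select("subject_id", "group", "condition", "seed", "recording")
}
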