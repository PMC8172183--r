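# Per-window biomarker feature sets. Every extractor returns a tidy feature
# tibble: metadata columns (subject_id, group, condition, window_index)
# followed by numeric feature columns, one row per 1-second window.

window_meta <- function(wrec) {
  tibble(
    subject_id = wrec$subject_id, group = wrec$group,
    condition = wrec$condition, window_index = wrec$window_index
  )
}

# Welch PSD for every window of an eeg_windows object; returns list(freq,
# psd: n_windows x channels x bins array)
windows_psd <- function(wrec) {
  n <- n_windows(wrec)
  first <- welch_psd(wrec$windows[, , 1], wrec$fs)
  arr <- array(NA_real_, dim = c(n, nrow(first$psd), length(first$freq)),
               dimnames = list(NULL, wrec$channels, NULL))
  arr[1, , ] <- first$psd
  if (n > 1) {
    for (i in 2:n) arr[i, , ] <- welch_psd(wrec$windows[, , i], wrec$fs)$psd
  }
  list(freq = first$freq, psd = arr)
}

#' Band-power features (alpha, beta, theta at Fz, Cz, Pz)
#'
#' Integrated Welch band power per 1-second window for the alpha (7-13 Hz),
#' beta (13-39 Hz) and theta (4-7 Hz) bands at the three midline channels.
#' Channels are looked up by label, so input channel order does not matter.
#'
#' @param wrec An `eeg_windows` object containing Fz, Cz and Pz.
#' @return A feature tibble with 9 feature columns ordered
#'   `(Fz, Cz, Pz) x (alpha, beta, theta)`, e.g. `Fz_alpha` ... `Pz_theta`.
#' @export
power_features <- function(wrec) {
  need <- c("Fz", "Cz", "Pz")
  if (!all(need %in% wrec$channels)) abort("power features need channels Fz, Cz and Pz")
  p <- windows_psd(wrec)
  df <- p$freq[2] - p$freq[1]
  bands <- eeg_bands() |> filter(.data$band %in% c("alpha", "beta", "theta"))
  bands <- bands[match(c("alpha", "beta", "theta"), bands$band), ]
  cols <- list()
  for (ch in need) {
    for (b in seq_len(nrow(bands))) {
      bins <- band_bins(p$freq, bands$lo[b], bands$hi[b])
      cols[[paste0(ch, "_", bands$band[b])]] <-
        rowSums(p$psd[, ch, bins, drop = FALSE], dims = 1) * df
    }
  }
  new_feature_tbl(window_meta(wrec), do.call(cbind, cols), "power")
}

#' Relative gamma (RG) features
#'
#' Per channel and window, the ratio of average gamma-band power (25-45 Hz)
#' to average slow-rhythm power (4-13 Hz), where "average power" is the mean
#' Welch PSD over the band's frequency bins. RG is dimensionless and invariant
#' to global amplitude scaling.
#'
#' @param wrec An `eeg_windows` object with `fs >= 90` Hz.
#' @param gamma_band,slow_band Numeric `c(lo, hi)` band edges in Hz. The slow
#'   band defaults to 4-13 Hz; a 4-23 Hz variant can be requested.
#' @return A feature tibble with columns `RG_Fz`, `RG_Cz`, `RG_Pz`. Windows
#'   with zero slow-band power are dropped with a warning naming them.
#' @export
relative_gamma <- function(wrec, gamma_band = c(25, 45), slow_band = c(4, 13)) {
  if (wrec$fs < 90) abort("relative gamma needs fs >= 90 Hz to resolve the 25-45 Hz band")
  need <- c("Fz", "Cz", "Pz")
  if (!all(need %in% wrec$channels)) abort("relative gamma needs channels Fz, Cz and Pz")
  p <- windows_psd(wrec)
  num <- sapply(need, function(ch) {
    rowMeans(p$psd[, ch, band_bins(p$freq, gamma_band[1], gamma_band[2]), drop = FALSE], dims = 1)
  })
  den <- sapply(need, function(ch) {
    rowMeans(p$psd[, ch, band_bins(p$freq, slow_band[1], slow_band[2]), drop = FALSE], dims = 1)
  })
  num <- matrix(num, ncol = 3); den <- matrix(den, ncol = 3)
  bad <- apply(den == 0, 1, any)
  if (any(bad)) {
    warn(sprintf("dropping %d window(s) with zero slow-band power (window_index %s)",
                 sum(bad), paste(wrec$window_index[bad], collapse = ", ")))
  }
  rg <- (num / den)[!bad, , drop = FALSE]
  colnames(rg) <- paste0("RG_", need)
  new_feature_tbl(window_meta(wrec)[!bad, ], rg, "rg")
}

#' Brain load index (BLI) feature
#'
#' Per window, the ratio of frontal-midline theta power to parietal-midline
#' alpha power, `Theta(Fz) / Alpha(Pz)` — the classic workload index: mental
#' load raises frontal theta and suppresses parietal alpha, so BLI rises
#' under stress.
#'
#' @param wrec An `eeg_windows` object containing Fz and Pz.
#' @return A feature tibble with a single `BLI` column. Windows with zero Pz
#'   alpha power are dropped with a warning naming them.
#' @export
brain_load_index <- function(wrec) {
  if (!all(c("Fz", "Pz") %in% wrec$channels)) abort("BLI needs channels Fz and Pz")
  p <- windows_psd(wrec)
  df <- p$freq[2] - p$freq[1]
  theta_fz <- rowSums(p$psd[, "Fz", band_bins(p$freq, 4, 7), drop = FALSE], dims = 1) * df
  alpha_pz <- rowSums(p$psd[, "Pz", band_bins(p$freq, 7, 13), drop = FALSE], dims = 1) * df
  bad <- alpha_pz == 0
  if (any(bad)) {
    warn(sprintf("dropping %d window(s) with zero Pz alpha power (window_index %s)",
                 sum(bad), paste(wrec$window_index[bad], collapse = ", ")))
  }
  bli <- matrix(theta_fz[!bad] / alpha_pz[!bad], ncol = 1,
                dimnames = list(NULL, "BLI"))
  new_feature_tbl(window_meta(wrec)[!bad, ], bli, "bli")
}

#' Raw-amplitude control features
#'
#' The degenerate control feature set: the raw per-sample amplitudes of the
#' window at Fz, Cz and Pz, flattened to one long row. Used to demonstrate
#' that raw EEG amplitude carries little condition information compared with
#' the spectral biomarkers.
#'
#' @param wrec An `eeg_windows` object.
#' @param n_per_channel Number of evenly spaced samples kept per channel.
#' @return A feature tibble with `3 * n_per_channel` feature columns.
#' @export
raw_amplitude_features <- function(wrec, n_per_channel = 25) {
  need <- c("Fz", "Cz", "Pz")
  idx <- round(seq(1, dim(wrec$windows)[2], length.out = n_per_channel))
  mat <- t(apply(wrec$windows[need, idx, , drop = FALSE], 3, identity))
  colnames(mat) <- paste0(rep(need, times = n_per_channel), "_t",
                          rep(seq_len(n_per_channel), each = 3))
  new_feature_tbl(window_meta(wrec), mat, "raw_amplitude")
}

#' Extract a feature set across a whole preprocessed cohort
#'
#' @param cohort_windows A tibble with a `windows` list-column, as returned by
#'   [preprocess_cohort()].
#' @param set One of `"power"`, `"rg"`, `"bli"`, `"raw_amplitude"`.
#' @return A single feature tibble with one row per window across all
#'   subject-condition pairs.
#' @export
extract_features <- function(cohort_windows,
                             set = c("power", "rg", "bli", "raw_amplitude")) {
  set <- match.arg(set)
  fn <- switch(set,
    power = power_features, rg = relative_gamma,
    bli = brain_load_index, raw_amplitude = raw_amplitude_features
  )
  out <- list_rbind(map(cohort_windows$windows, fn))
  attr(out, "feature_set") <- set
  class(out) <- c("eeg_features", class(out))
  out
}
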