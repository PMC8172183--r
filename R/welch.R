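# Welch power spectral density estimation.
#
# Convention: 0.5-second segments (125 samples at 250 Hz), 50% overlap,
# periodic Hann taper, one-sided PSD in uV^2/Hz. With 1-second windows this
# averages 3 periodograms at 2 Hz resolution, enough to cover the 4 Hz lower
# band edge.

hann_window <- function(n) 0.5 * (1 - cos(2 * pi * (seq_len(n) - 1) / n))

#' Welch PSD of a multi-channel window
#'
#' @param x Channels x samples numeric matrix (or a numeric vector, treated as
#'   one channel).
#' @param fs Sampling rate in Hz.
#' @param seg_len Segment length in samples; defaults to half a second.
#' @param overlap Fractional segment overlap.
#' @return A list with `freq` (Hz) and `psd`, a channels x frequency-bins
#'   matrix (one-sided, uV^2/Hz).
#' @export
welch_psd <- function(x, fs, seg_len = floor(fs / 2), overlap = 0.5) {
  if (is.vector(x)) x <- matrix(x, nrow = 1, dimnames = list("x1", NULL))
  n <- ncol(x)
  if (n < seg_len) abort("window shorter than one Welch segment")
  step <- max(1L, floor(seg_len * (1 - overlap)))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  w <- hann_window(seg_len)
  u <- sum(w^2)
  n_bins <- floor(seg_len / 2) + 1L

  acc <- matrix(0, nrow = nrow(x), ncol = n_bins)
  for (s in starts) {
    seg <- x[, s:(s + seg_len - 1L), drop = FALSE] * rep(w, each = nrow(x))
    spec <- Mod(t(stats::mvfft(t(seg))))^2
    acc <- acc + spec[, seq_len(n_bins), drop = FALSE]
  }
  psd <- acc / (length(starts) * fs * u)
  # one-sided: double everything except DC (and Nyquist when seg_len is even)
  dbl <- rep(2, n_bins)
  dbl[1] <- 1
  if (seg_len %% 2 == 0) dbl[n_bins] <- 1
  psd <- psd * rep(dbl, each = nrow(x))
  rownames(psd) <- rownames(x)
  list(freq = (seq_len(n_bins) - 1) * fs / seg_len, psd = psd)
}

band_bins <- function(freq, lo, hi) which(freq >= lo & freq < hi)

#' Integrated band power of one window
#'
#' Sums the Welch PSD over the band's frequency bins times the bin width,
#' giving integrated band power in uV^2 per channel. Bands are half-open
#' `[lo, hi)`.
#'
#' @inheritParams welch_psd
#' @param lo,hi Band edges in Hz; `hi` must not exceed the Nyquist frequency.
#' @return Named numeric vector of per-channel band power (uV^2).
#' @examples
#' t <- seq(0, 1, length.out = 251)[-251]
#' band_power(sin(2 * pi * 10 * t) * 2, fs = 250, lo = 7, hi = 13)
#' @export
band_power <- function(x, fs, lo, hi, seg_len = floor(fs / 2), overlap = 0.5) {
  if (lo >= hi) abort("`lo` must be below `hi`")
  if (hi > fs / 2) abort(sprintf("band [%g, %g) exceeds the Nyquist frequency %g Hz", lo, hi, fs / 2))
  p <- welch_psd(x, fs, seg_len, overlap)
  df <- p$freq[2] - p$freq[1]
  bins <- band_bins(p$freq, lo, hi)
  rowSums(p$psd[, bins, drop = FALSE]) * df
}

# mean PSD over band bins (the AvPower convention used in ratio features)
av_power <- function(psd, freq, lo, hi) {
  bins <- band_bins(freq, lo, hi)
  rowMeans(psd[, bins, drop = FALSE])
}
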