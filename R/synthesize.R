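#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the RNG seeded to `seed`, then restores the caller's RNG
#' state, so seeded steps never disturb the surrounding random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @export
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# zero-phase band-limited Gaussian noise with unit RMS
band_noise <- function(n, fs, lo, hi) {
  w <- c(lo, hi) / (fs / 2)
  bf <- signal::butter(2, w, type = "pass")
  x <- signal::filtfilt(bf, rnorm(n))
  x / sqrt(mean(x^2))
}

# 1/f^exponent power-law noise via frequency-domain shaping, unit RMS
pink_noise <- function(n, exponent) {
  x <- rnorm(n)
  xf <- fft(x)
  f <- seq_len(n) - 1
  f <- pmin(f, n - f) # two-sided frequency index
  scale <- ifelse(f == 0, 0, f^(-exponent / 2))
  x <- Re(fft(xf * scale, inverse = TRUE)) / n
  x / sqrt(mean(x^2))
}

#' Synthesize one EEG recording for a condition specification
#'
#' Each channel is a sum of four band-limited Gaussian-noise components
#' (theta, alpha, beta, gamma at the package band edges), scaled by the
#' condition's channel-by-band gain matrix and the per-band base amplitudes,
#' over a 1/f pink-noise background plus broadband white noise. Output is
#' deterministic given the seed.
#'
#' @param spec One row of [stress_protocol()] (a one-row tibble or a list with
#'   `condition`, `duration_s`, `noise_sd`, `pink_exponent`, `gains`).
#' @param subject_id,group Recording metadata.
#' @param fs Sampling rate in Hz; must be at least 100 so the gamma band is
#'   representable.
#' @param seed Integer seed.
#' @return An [eeg_recording()].
#' @examples
#' spec <- stress_protocol(1)[3, ]
#' rec <- synth_recording(spec, "s1", "control", fs = 250, seed = 7)
#' @export
synth_recording <- function(spec, subject_id, group, fs = 250, seed = 1L) {
  if (is_tibble(spec)) {
    if (nrow(spec) != 1) abort("`spec` must be a single condition row")
    spec <- as.list(spec)
    spec$gains <- spec$gains[[1]]
  }
  if (fs < 100) abort("`fs` must be >= 100 Hz: the gamma band (25-45 Hz) is unrepresentable below that")
  gains <- spec$gains
  if (any(gains < 0)) abort("band gains must be non-negative")
  n <- round(spec$duration_s * fs)
  if (n < 1) abort("duration too short")
  bands <- eeg_bands()
  channels <- rownames(gains)

  data <- with_seed(seed, {
    out <- matrix(0, nrow = length(channels), ncol = n,
                  dimnames = list(channels, NULL))
    for (ch in channels) {
      sig <- numeric(n)
      for (b in seq_len(nrow(bands))) {
        band <- bands$band[b]
        amp <- .band_base_rms[[band]] * gains[ch, band]
        if (amp > 0) sig <- sig + amp * band_noise(n, fs, bands$lo[b], bands$hi[b])
      }
      pink_sd <- spec$pink_sd %||% 4
      if (pink_sd > 0) sig <- sig + pink_sd * pink_noise(n, spec$pink_exponent)
      if (spec$noise_sd > 0) sig <- sig + spec$noise_sd * rnorm(n)
      out[ch, ] <- sig
    }
    out
  })

  rec <- eeg_recording(data, fs, subject_id, group, spec$condition, seed = as.integer(seed))
  rec$gains <- gains
  rec
}

#' Synthesize a cohort of recordings
#'
#' Generates `n_nurses + n_controls` subjects, each recorded under all four
#' protocol conditions. Inter-subject variability is emulated by multiplicative
#' log-normal jitter on every channel-by-band gain (jitter is drawn once per
#' subject and shared across that subject's conditions, so condition contrasts
#' are preserved within subject). Fully reproducible from `master_seed`.
#'
#' @param n_nurses,n_controls Subject counts per group (total must be >= 1).
#' @param protocol A protocol tibble from [stress_protocol()].
#' @param fs Sampling rate in Hz.
#' @param master_seed Integer seed controlling the whole cohort.
#' @param gain_jitter_sd Standard deviation of the log-normal gain jitter on
#'   the log scale; 0 disables inter-subject variability.
#' @return A tibble with columns `subject_id`, `group`, `condition`, `seed`
#'   and `recording` (list-column of [eeg_recording()]s), one row per
#'   subject-condition pair.
#' @export
synth_cohort <- function(n_nurses, n_controls, protocol = stress_protocol(1),
                         fs = 250, master_seed = 1L, gain_jitter_sd = 0.1) {
  n_nurses <- as.integer(n_nurses)
  n_controls <- as.integer(n_controls)
  if (n_nurses < 0 || n_controls < 0 || n_nurses + n_controls < 1) {
    abort("cohort must contain at least one subject")
  }
  subjects <- tibble(
    subject_id = c(
      sprintf("nurse%02d", seq_len(n_nurses)),
      sprintf("ctrl%02d", seq_len(n_controls))
    ),
    group = rep(c("nurse", "control"), c(n_nurses, n_controls))
  )
  n_sub <- nrow(subjects)
  n_cond <- nrow(protocol)
  g_template <- protocol$gains[[1]]

  draws <- with_seed(master_seed, {
    list(
      seeds = matrix(sample.int(.Machine$integer.max, n_sub * n_cond),
                     nrow = n_sub),
      jitter = array(exp(rnorm(n_sub * length(g_template), sd = gain_jitter_sd)),
                     dim = c(n_sub, nrow(g_template), ncol(g_template)))
    )
  })

  rows <- vector("list", n_sub * n_cond)
  k <- 0
  for (i in seq_len(n_sub)) {
    jit <- draws$jitter[i, , ]
    for (j in seq_len(n_cond)) {
      spec <- as.list(protocol[j, ])
      spec$gains <- spec$gains[[1]] * jit
      k <- k + 1
      rows[[k]] <- tibble(
        subject_id = subjects$subject_id[i],
        group = subjects$group[i],
        condition = spec$condition,
        seed = draws$seeds[i, j],
        recording = list(synth_recording(
          spec, subjects$subject_id[i], subjects$group[i], fs = fs,
          seed = draws$seeds[i, j]
        ))
      )
    }
  }
  list_rbind(rows)
}
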