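#' Default four-condition stress protocol
#'
#' Builds the condition specifications the synthetic generator consumes: a
#' 10-minute resting baseline, a 10-minute speech-preparation task, a 5-minute
#' public-speaking task and a 5-minute mental-arithmetic task. Stress
#' conditions modulate the spectral signature relative to baseline in the
#' direction the workload literature predicts: frontal-midline theta and
#' broadband gamma rise, parietal alpha falls.
#'
#' For a stress condition with intensity coefficient `c` (preparation 0.15,
#' arithmetic 0.30, speech 0.50 — speech is the strongest stressor), the Fz
#' theta gain and the gamma gain on all channels are multiplied by
#' `1 + c * stress_strength` and the Pz alpha gain is divided by the same
#' factor. At `stress_strength = 0` all four conditions share unit gains.
#'
#' @param stress_strength Non-negative dimensionless effect size. 0 means no
#'   condition differences; 1 is the package default study condition.
#' @param durations_s Named numeric vector of condition durations in seconds.
#' @param noise_sd Broadband white-noise RMS amplitude (microvolts).
#' @param pink_sd RMS amplitude of the 1/f background (microvolts).
#' @param pink_exponent Spectral slope of the 1/f background.
#' @return A tibble with one row per condition: `condition`, `duration_s`,
#'   `noise_sd`, `pink_exponent`, and `gains`, a list-column of channels x
#'   bands gain matrices (rows Fz/Cz/Pz, columns theta/alpha/beta/gamma).
#' @examples
#' stress_protocol(1)
#' @export
stress_protocol <- function(stress_strength = 1,
                            durations_s = c(
                              baseline = 600, preparation = 600,
                              speech = 300, arithmetic = 300
                            ),
                            noise_sd = 1,
                            pink_sd = 4,
                            pink_exponent = 1) {
  if (!is.numeric(stress_strength) || length(stress_strength) != 1 ||
      !is.finite(stress_strength) || stress_strength < 0) {
    abort("`stress_strength` must be a finite non-negative scalar")
  }
  conds <- c("baseline", "preparation", "speech", "arithmetic")
  if (!all(conds %in% names(durations_s))) {
    abort("`durations_s` must name all four conditions")
  }
  if (any(durations_s[conds] <= 0)) abort("durations must be positive")

  # condition intensity coefficients, monotone preparation < arithmetic < speech
  intensity <- c(baseline = 0, preparation = 0.15, arithmetic = 0.30, speech = 0.50)

  gains_for <- function(cond) {
    g <- matrix(1, nrow = 3, ncol = 4,
                dimnames = list(c("Fz", "Cz", "Pz"),
                                c("theta", "alpha", "beta", "gamma")))
    bump <- 1 + intensity[[cond]] * stress_strength
    g["Fz", "theta"] <- bump
    g[, "gamma"] <- bump
    g["Pz", "alpha"] <- 1 / bump
    g
  }

  tibble(
    condition = conds,
    duration_s = unname(durations_s[conds]),
    noise_sd = noise_sd,
    pink_sd = pink_sd,
    pink_exponent = pink_exponent,
    gains = map(conds, gains_for)
  )
}

#' Frequency bands used throughout the pipeline
#'
#' Theta 4-7 Hz, alpha 7-13 Hz, beta 13-39 Hz and gamma 25-45 Hz. Band
#' intervals are half-open `[lo, hi)` so the shared 7 and 13 Hz edges are not
#' double-counted.
#'
#' @return A tibble with columns `band`, `lo`, `hi` (Hz).
#' @export
eeg_bands <- function() {
  tibble(
    band = c("theta", "alpha", "beta", "gamma"),
    lo = c(4, 7, 13, 25),
    hi = c(7, 13, 39, 45)
  )
}

# per-band base RMS amplitudes (microvolts) at unit gain; together with the
# pink + white background these keep total RMS in a plausible 5-50 uV range
.band_base_rms <- c(theta = 3, alpha = 4, beta = 2, gamma = 1)

#' Per-band base RMS amplitudes of the generator
#'
#' The microvolt RMS each band component contributes at unit gain; the
#' effective band amplitude of a synthesized channel is this base value times
#' the condition's gain.
#'
#' @return Named numeric vector (theta, alpha, beta, gamma), in microvolts.
#' @export
band_base_rms <- function() .band_base_rms
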