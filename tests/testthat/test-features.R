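# brute-force periodogram oracle: plain FFT magnitude squared, no averaging,
# rectangular window; integrated band power = sum of one-sided PSD bins * df
oracle_band_power <- function(x, fs, lo, hi) {
  n <- length(x)
  psd <- Mod(fft(x))^2 / (n * fs)
  nb <- floor(n / 2) + 1
  psd <- psd[seq_len(nb)]
  dbl <- rep(2, nb); dbl[1] <- 1
  if (n %% 2 == 0) dbl[nb] <- 1
  psd <- psd * dbl
  freq <- (seq_len(nb) - 1) * fs / n
  sum(psd[freq >= lo & freq < hi]) * fs / n
}

test_that("Welch band power matches the analytic tone power and the periodogram oracle", {
  x <- tone(10, amp = 2)
  alpha <- band_power(x, 250, 7, 13)
  expect_equal(unname(alpha), 2, tolerance = 0.10) # A^2/2
  expect_equal(unname(alpha), oracle_band_power(x, 250, 7, 13), tolerance = 0.15)

  theta <- band_power(x, 250, 4, 7)
  expect_lt(unname(theta), 0.05 * unname(alpha))

  # an off-centre in-band tone still agrees with the oracle within 15%
  y <- tone(30, amp = 1.5)
  expect_equal(unname(band_power(y, 250, 25, 45)),
               oracle_band_power(y, 250, 25, 45), tolerance = 0.15)

  expect_equal(unname(band_power(rep(0, 250), 250, 7, 13)), 0)
  expect_error(band_power(x, 250, 100, 130), "Nyquist")
})

test_that("band power is additive over disjoint bands", {
  set.seed(5)
  x <- rnorm(250)
  whole <- band_power(x, 250, 4, 13)
  parts <- band_power(x, 250, 4, 7) + band_power(x, 250, 7, 13)
  expect_equal(unname(whole), unname(parts), tolerance = 1e-12)
})

test_that("power features have the documented layout and label-based lookup", {
  set.seed(6)
  w <- as_windows(matrix(rnorm(3 * 250 * 5), nrow = 3,
                         dimnames = list(c("Fz", "Cz", "Pz"), NULL)))
  pf <- power_features(w)
  expect_equal(nrow(pf), 5)
  expect_equal(
    feature_cols(pf),
    c("Fz_alpha", "Fz_beta", "Fz_theta", "Cz_alpha", "Cz_beta", "Cz_theta",
      "Pz_alpha", "Pz_beta", "Pz_theta")
  )
  expect_true(all(feature_matrix(pf) > 0))

  # permuting the channel rows leaves the features unchanged
  wp <- w
  wp$windows <- w$windows[c("Pz", "Fz", "Cz"), , , drop = FALSE]
  wp$channels <- c("Pz", "Fz", "Cz")
  expect_equal(feature_matrix(power_features(wp)), feature_matrix(pf))

  # identical windows give identical rows
  w2 <- w
  w2$windows[, , 2] <- w2$windows[, , 1]
  m <- feature_matrix(power_features(w2))
  expect_equal(m[2, ], m[1, ])
})

test_that("relative gamma is the AvPower ratio, near zero for slow tones, scale-free", {
  set.seed(7)
  w <- as_windows(matrix(rnorm(3 * 250 * 4), nrow = 3,
                         dimnames = list(c("Fz", "Cz", "Pz"), NULL)))
  rg <- relative_gamma(w)
  expect_equal(feature_cols(rg), c("RG_Fz", "RG_Cz", "RG_Pz"))

  # manual AvPower ratio on the first window
  p <- welch_psd(w$windows[, , 1], 250)
  num <- mean(p$psd["Fz", p$freq >= 25 & p$freq < 45])
  den <- mean(p$psd["Fz", p$freq >= 4 & p$freq < 13])
  expect_equal(rg$RG_Fz[1], num / den, tolerance = 1e-12)

  # a pure 10 Hz tone has leakage-level gamma only
  wt <- as_windows(tri_channel(tone(10, 2, dur = 3)))
  expect_lt(max(feature_matrix(relative_gamma(wt))), 1e-3)

  # global amplitude scaling cancels
  w3 <- w
  w3$windows <- w$windows * 3
  expect_equal(feature_matrix(relative_gamma(w3)), feature_matrix(rg),
               tolerance = 1e-12)

  slow <- as_windows(tri_channel(rnorm(2 * 80)), fs = 80)
  expect_error(relative_gamma(slow), "90 Hz")
})

test_that("BLI is Theta(Fz)/Alpha(Pz)", {
  # Fz carries a 5 Hz tone with power 3, Pz a 10 Hz tone with power 1.5
  data <- rbind(
    Fz = tone(5, sqrt(2 * 3)),
    Cz = tone(20, 1),
    Pz = tone(10, sqrt(2 * 1.5))
  )
  w <- as_windows(data)
  expect_equal(brain_load_index(w)$BLI, 2, tolerance = 0.05)

  # equal theta and alpha powers give BLI = 1
  eq <- rbind(Fz = tone(5, 2), Cz = tone(20, 1), Pz = tone(10, 2))
  expect_equal(brain_load_index(as_windows(eq))$BLI, 1, tolerance = 0.05)

  # zero Pz alpha power: row dropped with a diagnostic
  z <- rbind(Fz = tone(5, 2), Cz = tone(20, 1), Pz = rep(0, 250))
  expect_warning(out <- brain_load_index(as_windows(z)), "zero Pz alpha")
  expect_equal(nrow(out), 0)
})

test_that("generated cohorts yield finite features with the stress ordering", {
  bli <- cohort_features_small("bli")
  expect_true(all(is.finite(feature_matrix(bli))))
  by_cond <- dplyr::group_by(bli, condition) |>
    dplyr::summarise(m = mean(BLI))
  expect_gt(
    by_cond$m[by_cond$condition == "speech"],
    by_cond$m[by_cond$condition == "baseline"]
  )

  pf <- cohort_features_small("power")
  expect_true(all(is.finite(feature_matrix(pf))))
  expect_true(all(feature_matrix(pf) > 0))
  # 200 windows per subject-condition pair after partition 3
  counts <- dplyr::count(pf, subject_id, condition)
  expect_true(all(counts$n == 200))
})
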