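# Shared fixtures, built in code and cached for the duration of the test run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# channels x samples matrix holding the same signal on Fz, Cz, Pz
tri_channel <- function(x) {
  matrix(rep(x, each = 3), nrow = 3, dimnames = list(c("Fz", "Cz", "Pz"), NULL))
}

# a sinusoid with known integrated band power amp^2 / 2
tone <- function(freq, amp, fs = 250, dur = 1) {
  t <- seq(0, dur, by = 1 / fs)[seq_len(dur * fs)]
  amp * sin(2 * pi * freq * t)
}

# quick eeg_windows from a channels x samples matrix
as_windows <- function(data, fs = 250, condition = "baseline", window_s = 1) {
  rec <- eeg_recording(data, fs, "s1", "control", condition)
  window_recording(rec, preprocess_config(window_s = window_s))
}

# small preprocessed cohort at full protocol durations (expensive; cached)
cohort_windows_small <- function(strength = 1, seed = 42, n_nurses = 2, n_controls = 2) {
  key <- sprintf("cohort_%s_%s_%d_%d", strength, seed, n_nurses, n_controls)
  cached(key, {
    synth_cohort(n_nurses, n_controls, stress_protocol(strength),
                 fs = 250, master_seed = seed) |>
      preprocess_cohort(part = time_window_partition(3))
  })
}

cohort_features_small <- function(set, strength = 1, seed = 42,
                                  n_nurses = 2, n_controls = 2) {
  key <- sprintf("feat_%s_%s_%s_%d_%d", set, strength, seed, n_nurses, n_controls)
  cached(key, extract_features(
    cohort_windows_small(strength, seed, n_nurses, n_controls), set
  ))
}

# labelled Gaussian feature tibble with controllable class separation
gaussian_features <- function(n_per_class = 50, d = 6, sep = 0, seed = 1,
                              classes = c("baseline", "preparation", "speech", "arithmetic")) {
  set.seed(seed)
  n <- n_per_class * length(classes)
  X <- matrix(rnorm(n * d), n, d)
  cond <- rep(classes, each = n_per_class)
  centers <- matrix(rnorm(length(classes) * d, sd = sep), length(classes), d)
  X <- X + centers[match(cond, classes), ]
  colnames(X) <- paste0("f", seq_len(d))
  out <- dplyr::bind_cols(
    tibble::tibble(
      subject_id = "s1",
      group = rep(c("nurse", "control"), length.out = n),
      condition = cond,
      window_index = seq_len(n) - 1L
    ),
    tibble::as_tibble(X)
  )
  attr(out, "feature_set") <- "gaussian"
  class(out) <- c("eeg_features", class(out))
  out
}
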